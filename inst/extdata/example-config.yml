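# Example pipeline configuration for drgquant::read_config().
# Channel names must match the TIFF page names (sidecar or --channels).
pixel_area_um2: 1.0
channels:
  neuron_marker: PGP9.5
  mhcii: MHCII
  cd3: CD3
  cd4: CD4
  dapi: DAPI
  rfx1: RFX1
  ova: OVA
segmentation:
  shrink_px: 4
  grow_px: 7
  nonneuronal_mhcii_min: 25000
  # symbolic thresholds default to "otsu"; override with absolute AFU, e.g.
  # neuron_marker_threshold: 6000
puncta:
  min_area_px: 1.5
  delta_afu: 800
  polar_min_area_px: 2
  polar_fold: 1.7
morphometry:
  small_max_um: 25
  large_min_um: 30
rfx1_threshold: 37.19
isotype: false
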