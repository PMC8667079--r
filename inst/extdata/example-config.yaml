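# Example run configuration for the SLI scatterometry pipeline.
# All lengths carry explicit units in the key names; angles are degrees.
geometry:
  leds_per_side: 256
  pixel_pitch_mm: 1.8
  source_sample_distance_mm: 130
  sample_camera_distance_mm: 400
  kernel_size: 4            # LEDs per kernel side (n)
  kernels_per_side: 48      # kernel positions per side (m)
  object_pixel_size_um: 3.0
acquisition:
  shots: 1
  scan_order: row-major
  illumination_time_s: 1
  gain: 1
analysis:
  delta_phi: 1              # azimuthal profile step
  filter: sli-1deg          # preset (cutoff 0.04, width 0.125); or give numbers
  prominence_threshold: 0.08
  tip_fraction: 0.06
  pair_tolerance_deg: 35
  reflex_rotation: 90
  min_radius_px: 4
visualization:
  block: 40
  alpha: 0.1
  min_defined_fraction: 0.08
seed: 1
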