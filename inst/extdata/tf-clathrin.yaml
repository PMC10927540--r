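# Two-channel colocalization design: transferrin-like channel A spots on
# clathrin-like channel B structures with designed Mander's overlaps.
type: two_channel
pixel_size: 0.1
design:
  target_m1: 0.71    # A-in-B
  target_m2: 0.62    # B-in-A
  n_a: 100
  spot_sigma: 0.2    # um
  amplitude: 20000   # un-convolved peak counts
  threshold_frac: 0.01
  fov: 35            # um
psf: {wavelength: 561, na: 1.0}
noise: {read_sd: 3, background: 20}
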