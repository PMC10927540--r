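# Extended (continuous) peripheral labeling: a static crescent band at the
# cell edge plus dye-enriched clusters, one drifting at 7.5 nm/s, imaged
# for ~950 s. The kymograph path and ridge window are part of the fixture.
type: extended
pixel_size: 0.1
frame_interval: 5    # s
duration: 950        # s
fov: 20              # um
band:
  center: [10.0, 24.0]  # um; circle center below the field
  radius: 16.0          # um
  width: 2.5            # um
  theta_range: [-2.2, -0.9]  # radians
  intensity: 60         # counts per pixel in the band
clusters:
  x0: [6.0, 15.5]
  y0: [8.0, 8.3]
  speed: [7.5, 0.0]     # nm/s
  direction: [0.0, 0.0] # radians
  sigma: [0.3, 0.3]     # um
  amplitude: [150.0, 150.0]
kymo_path: [[2.0, 8.0], [18.0, 8.0]]  # um; straight cut along the drift
kymo_window: [3.2, 4.8]  # um along the path, bracketing the moving ridge at t=0
psf: {wavelength: 488, na: 1.0}
noise: {read_sd: 3, background: 20}
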