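# FRAP on the same supported-bilayer system: 1 um-diameter Gaussian bleach
# hole recovering into a uniform prebleach plateau.
type: frap
D_true: 0.045        # um^2/s
prebleach_level: 150 # plateau counts above background
bleach_depth: 120    # hole depth, counts
sigma0: 0.42463      # um; 1 um FWHM bleach spot
pixel_size: 0.1
frame_interval: 0.13
n_frames: 30
n_prebleach: 5
fov: 8
n_series: 30
psf: {wavelength: 488, na: 1.0}
noise: {read_sd: 3, background: 20}
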