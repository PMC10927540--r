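# FRAP on the live COS-7 plasma membrane: 1 um bleach spot, faster
# recovery than the model bilayer.
type: frap
D_true: 0.35
prebleach_level: 600
bleach_depth: 500
sigma0: 0.42463
pixel_size: 0.1
frame_interval: 0.5
n_frames: 12
n_prebleach: 5
fov: 16
n_series: 8
psf: {wavelength: 488, na: 1.0}
noise: {read_sd: 3, background: 20}
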