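# Punctual labeling of GM1 in a live COS-7 plasma membrane: faster
# diffusion, 0.7 s frame duration, brighter labeling pulse.
type: punctual
D_true: 0.32
amplitude: 2000
sigma0: 0.42463
pixel_size: 0.1
frame_interval: 0.7
n_frames: 16
fov: 16
n_series: 8
psf: {wavelength: 488, na: 1.0}
noise: {read_sd: 3, background: 20}
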