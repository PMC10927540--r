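# Punctual labeling of GM1 on a supported lipid bilayer: a 1 um labeled
# spot (FWHM) spreading by free 2D diffusion, confocal frame cadence 130 ms.
type: punctual
D_true: 0.048        # um^2/s, ground-truth membrane diffusivity
amplitude: 200       # initial un-convolved peak, counts
sigma0: 0.42463      # um; FWHM = 1 um spot footprint
pixel_size: 0.1      # um
frame_interval: 0.13 # s
n_frames: 30
fov: 8               # um
n_series: 30         # replicate measurements in the ensemble
psf: {wavelength: 488, na: 1.0}
noise: {read_sd: 3, background: 20}
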