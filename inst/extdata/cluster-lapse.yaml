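# Coalescing receptor-cluster time lapse in a 15 x 15 um^2 membrane patch.
type: clusters
n0: 40
D_cluster: 0.02        # um^2/s
coalescence_radius: 0.4  # um
field_size: 15         # um
duration: 360          # s
frame_interval: 5      # s
unit_intensity: 500    # integrated counts per labeled receptor
pixel_size: 0.1
psf: {wavelength: 640, na: 1.0}
noise: {read_sd: 3, background: 20}
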