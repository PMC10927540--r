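# 1 um inner-diameter aperture pair (rim-touching separation) at the
# reference confinement ratio.
type: device
geometry: {inner_diameter_inj: 1, inner_diameter_asp: 1, wall_thickness: 1}
flow: {Q_inj: 0.16, Q_asp: 0.53333333}
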