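# Example dipscreen parameter file: octenidine vs an anionic PG membrane
lipid = PG
agent = OCT
box_lx = 80
box_ly = 80
apl = 64
half_thickness = 20
dt = 1e-15
n_steps = 500000
seed = 1
z_start = 45
n_replicates = 10
output_dir = results
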