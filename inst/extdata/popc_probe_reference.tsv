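# Published reference values for a hydrophobic probe crossing a POPC
# bilayer with embedded phytochemicals at 1:10 (CUR24: 2:10) compound:lipid
# ratio, from atomistic umbrella-sampling simulations (reduced 22-window
# monolayer-referenced protocol, 5 replicates).
# permeability in cm/s; barriers in kcal/mol; errors are jackknife SE.
system	permeability	permeability_se	dg_entry	dg_entry_se	dg_exit	dg_exit_se
POPC	4.4	0.4	2.9	0.1	7.1	0.1
RES	4.5	0.3	2.5	0.1	6.6	0.1
NOT	5.6	0.6	2.3	0.0	7.1	0.2
CUR	5.0	0.5	2.4	0.0	6.6	0.2
CUR24	5.7	0.3	2.3	0.0	6.3	0.1
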