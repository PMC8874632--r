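molecule_id,functional,solvent_name,solvent_dielectric,charge,multiplicity,total_energy,energy_unit,homo,lumo,somo
Veraguamide A,MN12SX,H2O,78.36,0,1,,eV,-6.635,-0.884,
Veraguamide A,MN12SX,H2O,78.36,1,2,,eV,,,
Veraguamide A,MN12SX,H2O,78.36,-1,2,,eV,,,-0.892
Veraguamide B,MN12SX,H2O,78.36,0,1,,eV,-6.637,-0.942,
Veraguamide B,MN12SX,H2O,78.36,1,2,,eV,,,
Veraguamide B,MN12SX,H2O,78.36,-1,2,,eV,,,-0.912
Veraguamide C,MN12SX,H2O,78.36,0,1,,eV,-6.812,-0.993,
Veraguamide C,MN12SX,H2O,78.36,1,2,,eV,,,
Veraguamide C,MN12SX,H2O,78.36,-1,2,,eV,,,-0.946
Veraguamide D,MN12SX,H2O,78.36,0,1,,eV,-6.661,-0.748,
Veraguamide D,MN12SX,H2O,78.36,1,2,,eV,,,
Veraguamide D,MN12SX,H2O,78.36,-1,2,,eV,,,-0.759
Veraguamide E,MN12SX,H2O,78.36,0,1,,eV,-6.873,-0.717,
Veraguamide E,MN12SX,H2O,78.36,1,2,,eV,,,
Veraguamide E,MN12SX,H2O,78.36,-1,2,,eV,,,-0.702
Veraguamide F,MN12SX,H2O,78.36,0,1,,eV,-6.717,-1.016,
Veraguamide F,MN12SX,H2O,78.36,1,2,,eV,,,
Veraguamide F,MN12SX,H2O,78.36,-1,2,,eV,,,-0.972
Veraguamide G,MN12SX,H2O,78.36,0,1,,eV,-6.697,-0.771,
Veraguamide G,MN12SX,H2O,78.36,1,2,,eV,,,
Veraguamide G,MN12SX,H2O,78.36,-1,2,,eV,,,-0.768
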