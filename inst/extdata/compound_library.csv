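name,formula,adducts,expected_mz,source
6-bromoisatin (6Br),C8H4BrNO2,[M-H]+;[M+K]+,224.9/226.9,natural extract monomer
tyrindoleninone (Tyr),C9H6BrNOS,[M+H]+;[MH+Na]+;[M-H]+,254.9/256.9,natural extract monomer
"6,6'-dibromoindigo (TP)",C16H8Br2N2O2,[M+H]+;[M+Na]+;[M]+,417.9/419.9/421.9,natural extract dimer
"6,6'-dibromoindirubin (DBI)",C16H8Br2N2O2,[M+H]+;[M+Na]+;[M]+,417.9/419.9/421.9,natural extract dimer
M1,,,301.902/303.906,mono-Br stomach metabolite
M3 (diethylamino-6Br),C12H18BrN2O2,[M]+,301.0549/303.0529,faecal extract metabolite
M17 (methylated di-Br dimer),,,432.963,stomach/ileum dimer
6Br acid-condensation dimer (alias a),,,419.891,di-Br dimer centre alias
6Br acid-condensation dimer (alias b),,,418.891,di-Br dimer centre alias
M22,,,488.955/490.967,ileum monomer pair
M23,,,512.956,ileum dimer centre
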