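lipid,pressure_mN_m,area_A2,potential_mV,dipole_mD,potential_derived,dipole_derived,subphase,source
DOPC,20,78,306,632,FALSE,FALSE,H2O,smaby1990
DOPC,30,70,329,610,FALSE,FALSE,H2O,smaby1990
DOPC,35,70,NA,850,FALSE,FALSE,"0.1 M NaCl, pH 6",beitinger1989
DOPC,45,59,311,486,TRUE,FALSE,H2O,vogel1988
DOPC,45,58,NA,463,FALSE,FALSE,"PBS, pH 6.6",vogel1988
DOPC,NA,NA,384,NA,FALSE,FALSE,1 mM KCl,oliveira1998
DPPC,10,69,NA,469,FALSE,FALSE,"PBS, pH 6.6",vogel1988
DPPC,20,46,400,488,FALSE,TRUE,H2O,taylor1990
DPPC,30,44,600,700,FALSE,TRUE,H2O,taylor1990
DPPC,35,42,700,780,FALSE,TRUE,H2O,taylor1990
DPPC,35,45,NA,700,FALSE,FALSE,"0.1 M NaCl, pH 6",beitinger1989
DPPC,NA,NA,460,NA,FALSE,FALSE,1 mM KCl,oliveira1998
DPPC,23,NA,640,NA,FALSE,FALSE,simulation,md_simulation
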