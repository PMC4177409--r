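code,analyte,foodstuff,limit_value,limit_unit,legislation
Cd 3.2.5,Cd,Muscle meat of fish,0.05,mg/kg w.w.,Reg.1881/2006/CE
Cd 3.2.6,Cd,Muscle meat of listened fish,0.1,mg/kg w.w.,Reg.1881/2006/CE
Cd 3.2.8,Cd,Crustaceans,0.5,mg/kg w.w.,Reg.1881/2006/CE
Cd 3.2.9,Cd,Bivalve molluscs,1,mg/kg w.w.,Reg.1881/2006/CE
Cd 3.2.10,Cd,Cephalopods,1,mg/kg w.w.,Reg.1881/2006/CE
Hg 3.3.1,Hg,Fishery products and muscle meat of fish,0.5,mg/kg w.w.,Reg.1881/2006/CE
Hg 3.3.2,Hg,Muscle meat of listened fish,1,mg/kg w.w.,Reg.1881/2006/CE
Pb 3.1.5,Pb,Muscle meat of fish,0.3,mg/kg w.w.,Reg.1881/2006/CE
Pb 3.1.6,Pb,Crustaceans,0.5,mg/kg w.w.,Reg.1881/2006/CE
Pb 3.1.7,Pb,Bivalve molluscs,1.5,mg/kg w.w.,Reg.1881/2006/CE
Pb 3.1.8,Pb,Cephalopods,1,mg/kg w.w.,Reg.1881/2006/CE
Dioxins 5.3,Dioxins,Muscle meat of fish and Bivalve molluscs,3.5,pg/g w.w.,Reg.1259/2011/CE
Sum dioxins and dioxin like PCBs 5.3,Sum dioxins and dl-PCBs,Muscle meat of fish and Bivalve molluscs,6.5,pg/g w.w.,Reg.1259/2011/CE
Benzo(a)pyrene 6.1.4,Benzo(a)pyrene,Muscle meat of fish,2,µg/kg w.w.,Reg.1881/2006/CE
Benzo(a)pyrene 6.1.5,Benzo(a)pyrene,Crustaceans and Cephalopods,5,µg/kg w.w.,Reg.1881/2006/CE
Benzo(a)pyrene 6.1.6,Benzo(a)pyrene,Bivalve molluscs,5,µg/kg w.w.,Reg.835/2011/CE
Sum PAH 6.1.6,Sum of 4 PAHs,Bivalve molluscs,30,µg/kg w.w.,Reg.835/2011/CE
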