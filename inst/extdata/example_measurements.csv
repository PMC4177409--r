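station_id,lon,lat,year,species,tissue,category_code,concentration,unit,below_loq,loq,subregion
ST0001,14.079373456654139,44.207347268983725,2010,Mytilus galloprovincialis,soft tissue,Hg 3.3.1,0.26925066944222453,mg/kg w.w.,FALSE,NA,synthetic
ST0001,14.079373456654139,44.207347268983725,2011,Mytilus galloprovincialis,soft tissue,Hg 3.3.1,0.49334255937627863,mg/kg w.w.,FALSE,NA,synthetic
ST0002,13.313346920069307,45.25780600048602,2010,Mytilus galloprovincialis,soft tissue,Hg 3.3.1,0.29868272358181935,mg/kg w.w.,FALSE,NA,synthetic
ST0002,13.313346920069307,45.25780600048602,2011,Mytilus galloprovincialis,soft tissue,Hg 3.3.1,0.3008638398520518,mg/kg w.w.,FALSE,NA,synthetic
ST0003,15.305627038353123,43.00008225850761,2010,Mytilus galloprovincialis,soft tissue,Hg 3.3.1,0.24304344908788525,mg/kg w.w.,FALSE,NA,synthetic
ST0003,15.305627038353123,43.00008225850761,2011,Mytilus galloprovincialis,soft tissue,Hg 3.3.1,0.3420413235899307,mg/kg w.w.,FALSE,NA,synthetic
ST0004,18.803872301825322,41.514654390327635,2010,Mytilus galloprovincialis,soft tissue,Hg 3.3.1,0.3391373928862314,mg/kg w.w.,FALSE,NA,synthetic
ST0004,18.803872301825322,41.514654390327635,2011,Mytilus galloprovincialis,soft tissue,Hg 3.3.1,0.31875940989358115,mg/kg w.w.,FALSE,NA,synthetic
ST0001,14.079373456654139,44.207347268983725,2010,Mytilus galloprovincialis,soft tissue,Cd 3.2.9,0.6519331223298276,mg/kg w.w.,FALSE,NA,synthetic
ST0001,14.079373456654139,44.207347268983725,2011,Mytilus galloprovincialis,soft tissue,Cd 3.2.9,0.7247243088101359,mg/kg w.w.,FALSE,NA,synthetic
ST0002,13.313346920069307,45.25780600048602,2010,Mytilus galloprovincialis,soft tissue,Cd 3.2.9,0.5707806745266862,mg/kg w.w.,FALSE,NA,synthetic
ST0002,13.313346920069307,45.25780600048602,2011,Mytilus galloprovincialis,soft tissue,Cd 3.2.9,0.5153174034800376,mg/kg w.w.,FALSE,NA,synthetic
ST0003,15.305627038353123,43.00008225850761,2010,Mytilus galloprovincialis,soft tissue,Cd 3.2.9,0.5705719386720005,mg/kg w.w.,FALSE,NA,synthetic
ST0003,15.305627038353123,43.00008225850761,2011,Mytilus galloprovincialis,soft tissue,Cd 3.2.9,0.6674024772779023,mg/kg w.w.,FALSE,NA,synthetic
ST0004,18.803872301825322,41.514654390327635,2010,Mytilus galloprovincialis,soft tissue,Cd 3.2.9,0.6460271162097201,mg/kg w.w.,FALSE,NA,synthetic
ST0004,18.803872301825322,41.514654390327635,2011,Mytilus galloprovincialis,soft tissue,Cd 3.2.9,0.579236418705636,mg/kg w.w.,FALSE,NA,synthetic
ST0001,14.079373456654139,44.207347268983725,2010,Mytilus galloprovincialis,soft tissue,Benzo(a)pyrene 6.1.6,4.212925094345481,µg/kg w.w.,FALSE,NA,synthetic
ST0001,14.079373456654139,44.207347268983725,2011,Mytilus galloprovincialis,soft tissue,Benzo(a)pyrene 6.1.6,3.5613680630749416,µg/kg w.w.,FALSE,NA,synthetic
ST0002,13.313346920069307,45.25780600048602,2010,Mytilus galloprovincialis,soft tissue,Benzo(a)pyrene 6.1.6,3.6807261328148053,µg/kg w.w.,FALSE,NA,synthetic
ST0002,13.313346920069307,45.25780600048602,2011,Mytilus galloprovincialis,soft tissue,Benzo(a)pyrene 6.1.6,3.1412542470736113,µg/kg w.w.,FALSE,NA,synthetic
ST0003,15.305627038353123,43.00008225850761,2010,Mytilus galloprovincialis,soft tissue,Benzo(a)pyrene 6.1.6,3.479885521207109,µg/kg w.w.,FALSE,NA,synthetic
ST0003,15.305627038353123,43.00008225850761,2011,Mytilus galloprovincialis,soft tissue,Benzo(a)pyrene 6.1.6,4.95411999334842,µg/kg w.w.,FALSE,NA,synthetic
ST0004,18.803872301825322,41.514654390327635,2010,Mytilus galloprovincialis,soft tissue,Benzo(a)pyrene 6.1.6,4.067886309861762,µg/kg w.w.,FALSE,NA,synthetic
ST0004,18.803872301825322,41.514654390327635,2011,Mytilus galloprovincialis,soft tissue,Benzo(a)pyrene 6.1.6,3.135564634529829,µg/kg w.w.,FALSE,NA,synthetic
ST0001,14.079373456654139,44.207347268983725,2010,Engraulis encrasicolus,muscle,Sum dioxins and dioxin like PCBs 5.3,3.532590588656942,pg/g w.w.,FALSE,NA,synthetic
ST0001,14.079373456654139,44.207347268983725,2011,Engraulis encrasicolus,muscle,Sum dioxins and dioxin like PCBs 5.3,4.104646987227402,pg/g w.w.,FALSE,NA,synthetic
ST0002,13.313346920069307,45.25780600048602,2010,Engraulis encrasicolus,muscle,Sum dioxins and dioxin like PCBs 5.3,4.1605276295298905,pg/g w.w.,FALSE,NA,synthetic
ST0002,13.313346920069307,45.25780600048602,2011,Engraulis encrasicolus,muscle,Sum dioxins and dioxin like PCBs 5.3,4.44171707737839,pg/g w.w.,FALSE,NA,synthetic
ST0003,15.305627038353123,43.00008225850761,2010,Engraulis encrasicolus,muscle,Sum dioxins and dioxin like PCBs 5.3,4.454646708952316,pg/g w.w.,FALSE,NA,synthetic
ST0003,15.305627038353123,43.00008225850761,2011,Engraulis encrasicolus,muscle,Sum dioxins and dioxin like PCBs 5.3,4.649581974347457,pg/g w.w.,FALSE,NA,synthetic
ST0004,18.803872301825322,41.514654390327635,2010,Engraulis encrasicolus,muscle,Sum dioxins and dioxin like PCBs 5.3,4.945855416338987,pg/g w.w.,FALSE,NA,synthetic
ST0004,18.803872301825322,41.514654390327635,2011,Engraulis encrasicolus,muscle,Sum dioxins and dioxin like PCBs 5.3,6.523582879506368,pg/g w.w.,FALSE,NA,synthetic
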