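name,dtxsid,smiles,exp_oecd2021,exp_oecd2018,exp_tsca2021,exp_pfasstruct_v1,exp_pfasstruct_v4,exp_ccl5,exp_pfasstruct_v5,exp_pct_f_excl_h,exp_pct_f_all_atoms,exp_mass_pct,note
methane,,C,FALSE,,,,,,FALSE,,,,no C-F bond; negative everywhere
carbon tetrafluoride,DTXSID2041757,FC(F)(F)F,TRUE,,,,,,TRUE,,,,fully fluorinated carbon
fluoroform,,FC(F)F,FALSE,,,,,,TRUE,,,,carbon carries H; 75% fluorine excluding H
difluoromethane,DTXSID6029597,FCF,FALSE,,,,,,,,,,carbon not fully fluorinated
chlorotrifluoromethane,DTXSID4052500,ClC(F)(F)F,FALSE,,,,,,,,,,attached chlorine defeats the fully fluorinated test
bromotrifluoromethane,,BrC(F)(F)F,FALSE,,,,,,,,,,attached bromine defeats the fully fluorinated test
hexafluoroethane,,FC(F)(F)C(F)(F)F,TRUE,,,,,,TRUE,,,,unambiguous PFAS
tetrafluoroethene,,FC(F)=C(F)F,FALSE,,,,,,TRUE,67,,,unsaturated monomer: no structural definition fires; 67% fluorine
perfluorobutanoic acid,DTXSID4059916,OC(=O)C(F)(F)C(F)(F)C(F)(F)F,TRUE,TRUE,TRUE,,,,TRUE,,50,62,worked formula example; counting all atoms 7/14 = 50%
"perfluorobutanoate, sodium salt",DTXSID70880179,[Na+].[O-]C(=O)C(F)(F)C(F)(F)C(F)(F)F,TRUE,,TRUE,,,,TRUE,,50,56,"complete salt: net charge zero, fractions match the acid"
"perfluorobutanoate, silver salt",DTXSID70880199,[Ag+].[O-]C(=O)C(F)(F)C(F)(F)C(F)(F)F,TRUE,,TRUE,,,,TRUE,,50,41,heavy counter-ion depresses the mass fraction only
6:2 fluorotelomer alcohol,DTXSID5044572,OCCC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F,TRUE,TRUE,,,,,TRUE,,,67.8,"fluorotelomer: perfluorohexyl tail, ethanol head"
"1,1,2,2-tetrachloro-1,3,3,3-tetrafluoropropane",DTXSID10547496,ClC(Cl)(F)C(Cl)(Cl)C(F)(F)F,TRUE,,FALSE,,FALSE,,TRUE,36,,,C3Cl4F4 isomer with one fully fluorinated carbon
"1,1,2,2-tetrafluorotetrachloropropane",DTXSID2062296,ClC(F)(F)C(F)(F)C(Cl)(Cl)Cl,TRUE,,TRUE,,TRUE,,TRUE,36,,,the only C3Cl4F4 isomer fitting the v4 substructures
"1,2,2,3-tetrachlorotetrafluoropropane",DTXSID30865482,ClC(F)(F)C(Cl)(Cl)C(Cl)(F)F,FALSE,,FALSE,,FALSE,,TRUE,36,,,every fluorinated carbon also carries chlorine
"1,1,2,3-tetrachloro-1,2,3,3-tetrafluoropropane",DTXSID50547495,ClC(Cl)(F)C(Cl)(F)C(Cl)(F)F,FALSE,,,,,,TRUE,36,,,"no fully fluorinated carbon; the halogen-permissive R-group reading makes the CF2Cl-CFCl< unit match the codified TSCA/v4 patterns, so no TSCA/v4 verdict is asserted for this isomer"
"4,4-difluoroheptane",DTXSID00509568,CCCC(F)(F)CCC,TRUE,,,,,,FALSE,,,,an isolated CF2 satisfies the 2021 OECD definition
"1,7-difluoroheptane",DTXSID20219354,FCCCCCCCF,FALSE,,,,,,FALSE,,,,terminal CH2F carbons carry hydrogen
trifluoroacetic acid,,OC(=O)C(F)(F)F,TRUE,FALSE,FALSE,FALSE,FALSE,,TRUE,,,,the v3-only substructure compound; three F fails the v1 count gate
"1,1,1,4,4,4-hexafluoro-2,3-diphenylbutane-2,3-diol",DTXSID40313106,OC(c1ccccc1)(C(F)(F)F)C(O)(c1ccccc1)C(F)(F)F,,,,,FALSE,,FALSE,25,,,only 25% fluorine and no v5 substructure
tetrakis(trifluoromethoxy)methane,,FC(F)(F)OC(OC(F)(F)F)(OC(F)(F)F)OC(F)(F)F,,,,,FALSE,,TRUE,,,,needs a CF3-O-C-O-CF3 substructure absent from v4
"1,1,1-trifluoroethane",,CC(F)(F)F,,,,,,,,,,,trivially fluorinated: a lone CF3
"1,1,1,4,4,4-hexafluorobutane",,FC(F)(F)CCC(F)(F)F,,,,,,,,,,,trivially fluorinated: two CF3 not sharing a carbon
"2-(trifluoromethyl)-1,1,1-trifluoropropane",,CC(C(F)(F)F)C(F)(F)F,,,,,TRUE,,,,,,two CF3 on one carbon: retained in gap analysis; branched v4 unit
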