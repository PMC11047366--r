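# Chemical-component dictionary subset for the COQ2 case study.
# SYNTHETIC RECONSTRUCTION: covers the components observed in the
# ligand-bound homolog structures (4OD5_A, 4TQ3_B, 6M31_B, 8DJM_B,
# 7Q21_f) plus the two query substrates. SMILES were written from the
# published chemical identity of each component, not copied from the
# wwPDB dictionary; AJP (digitonin) and CDL (cardiolipin) are
# class-accurate approximations of the deposited stereochemistry.
#
data_5TR
_chem_comp.id 5TR
_chem_comp.name "undecaprenyl phosphate"
loop_
_pdbx_chem_comp_descriptor.comp_id
_pdbx_chem_comp_descriptor.type
_pdbx_chem_comp_descriptor.program
_pdbx_chem_comp_descriptor.program_version
_pdbx_chem_comp_descriptor.descriptor
5TR SMILES_CANONICAL CACTVS 3.385 "CC(C)=CCC/C(C)=C/CC/C(C)=C/CC/C(C)=C\CC/C(C)=C\CC/C(C)=C\CC/C(C)=C\CC/C(C)=C\CC/C(C)=C\CC/C(C)=C\CC/C(C)=C\COP(O)(O)=O"
5TR SMILES ACDLabs 12.01 "CC(C)=CCCC(C)=CCCC(C)=CCCC(C)=CCCC(C)=CCCC(C)=CCCC(C)=CCCC(C)=CCCC(C)=CCCC(C)=CCCC(C)=CCOP(O)(O)=O"
#
data_GPP
_chem_comp.id GPP
_chem_comp.name "GERANYL DIPHOSPHATE"
loop_
_pdbx_chem_comp_descriptor.comp_id
_pdbx_chem_comp_descriptor.type
_pdbx_chem_comp_descriptor.program
_pdbx_chem_comp_descriptor.program_version
_pdbx_chem_comp_descriptor.descriptor
GPP SMILES_CANONICAL CACTVS 3.341 "CC(C)=CCC/C(C)=C/COP(O)(=O)OP(O)(O)=O"
GPP SMILES CACTVS 3.341 "CC(C)=CCCC(C)=CCOP(O)(=O)OP(O)(O)=O"
#
data_GST
_chem_comp.id GST
_chem_comp.name "GERANYL S-THIOLODIPHOSPHATE"
loop_
_pdbx_chem_comp_descriptor.comp_id
_pdbx_chem_comp_descriptor.type
_pdbx_chem_comp_descriptor.program
_pdbx_chem_comp_descriptor.program_version
_pdbx_chem_comp_descriptor.descriptor
GST SMILES_CANONICAL CACTVS 3.341 "CC(C)=CCC/C(C)=C/CSP(O)(=O)OP(O)(O)=O"
#
data_PHB
_chem_comp.id PHB
_chem_comp.name "P-HYDROXYBENZOIC ACID"
loop_
_pdbx_chem_comp_descriptor.comp_id
_pdbx_chem_comp_descriptor.type
_pdbx_chem_comp_descriptor.program
_pdbx_chem_comp_descriptor.program_version
_pdbx_chem_comp_descriptor.descriptor
PHB SMILES_CANONICAL "OpenEye OEToolkits" 1.5.0 "Oc1ccc(cc1)C(O)=O"
PHB SMILES_CANONICAL CACTVS 3.341 "OC(=O)c1ccc(O)cc1"
#
data_MG
_chem_comp.id MG
_chem_comp.name "MAGNESIUM ION"
loop_
_pdbx_chem_comp_descriptor.comp_id
_pdbx_chem_comp_descriptor.type
_pdbx_chem_comp_descriptor.program
_pdbx_chem_comp_descriptor.program_version
_pdbx_chem_comp_descriptor.descriptor
MG SMILES_CANONICAL CACTVS 3.341 "[Mg+2]"
#
data_PO4
_chem_comp.id PO4
_chem_comp.name "PHOSPHATE ION"
loop_
_pdbx_chem_comp_descriptor.comp_id
_pdbx_chem_comp_descriptor.type
_pdbx_chem_comp_descriptor.program
_pdbx_chem_comp_descriptor.program_version
_pdbx_chem_comp_descriptor.descriptor
PO4 SMILES_CANONICAL CACTVS 3.341 "[O-]P([O-])([O-])=O"
#
data_LDA
_chem_comp.id LDA
_chem_comp.name "LAURYL DIMETHYLAMINE-N-OXIDE"
loop_
_pdbx_chem_comp_descriptor.comp_id
_pdbx_chem_comp_descriptor.type
_pdbx_chem_comp_descriptor.program
_pdbx_chem_comp_descriptor.program_version
_pdbx_chem_comp_descriptor.descriptor
LDA SMILES_CANONICAL CACTVS 3.341 "CCCCCCCCCCCC[N+](C)(C)[O-]"
#
data_MPG
_chem_comp.id MPG
_chem_comp.name "[(Z)-octadec-9-enyl] (2R)-2,3-bis(oxidanyl)propanoate"
loop_
_pdbx_chem_comp_descriptor.comp_id
_pdbx_chem_comp_descriptor.type
_pdbx_chem_comp_descriptor.program
_pdbx_chem_comp_descriptor.program_version
_pdbx_chem_comp_descriptor.descriptor
MPG SMILES_CANONICAL CACTVS 3.385 "CCCCCCCC/C=C\CCCCCCCCOC(=O)[C@@H](O)CO"
#
data_Y01
_chem_comp.id Y01
_chem_comp.name "CHOLESTEROL HEMISUCCINATE"
loop_
_pdbx_chem_comp_descriptor.comp_id
_pdbx_chem_comp_descriptor.type
_pdbx_chem_comp_descriptor.program
_pdbx_chem_comp_descriptor.program_version
_pdbx_chem_comp_descriptor.descriptor
Y01 SMILES_CANONICAL CACTVS 3.370 "CC(C)CCC[C@@H](C)[C@H]1CC[C@H]2[C@@H]3CC=C4C[C@@H](OC(=O)CCC(O)=O)CC[C@]4(C)[C@H]3CC[C@]12C"
#
data_AJP
_chem_comp.id AJP
_chem_comp.name "digitonin"
loop_
_pdbx_chem_comp_descriptor.comp_id
_pdbx_chem_comp_descriptor.type
_pdbx_chem_comp_descriptor.program
_pdbx_chem_comp_descriptor.program_version
_pdbx_chem_comp_descriptor.descriptor
AJP SMILES_CANONICAL CACTVS 3.385 "CC1CCC2(OC1)OC1CC3C4CCC5CC(OC6OC(CO)C(OC7OC(CO)C(O)C(OC8OC(CO)C(O)C(O)C8O)C7OC7OC(CO)C(O)C(O)C7O)C(O)C6OC6OCC(O)C(O)C6O)C(O)CC5(C)C4CC(O)C3(C)C1C2C"
#
data_CDL
_chem_comp.id CDL
_chem_comp.name "CARDIOLIPIN"
loop_
_pdbx_chem_comp_descriptor.comp_id
_pdbx_chem_comp_descriptor.type
_pdbx_chem_comp_descriptor.program
_pdbx_chem_comp_descriptor.program_version
_pdbx_chem_comp_descriptor.descriptor
CDL SMILES_CANONICAL CACTVS 3.385 "CCCCCCCCCCCCCCCC(=O)OC[C@H](COP(O)(=O)OC[C@@H](O)COP(O)(=O)OC[C@H](COC(=O)CCCCCCCCCCCCCCC)OC(=O)CCCCCCCCCCCCCCC)OC(=O)CCCCCCCCCCCCCCC"
#
data_7PH
_chem_comp.id 7PH
_chem_comp.name "phosphatidic acid"
loop_
_pdbx_chem_comp_descriptor.comp_id
_pdbx_chem_comp_descriptor.type
_pdbx_chem_comp_descriptor.program
_pdbx_chem_comp_descriptor.program_version
_pdbx_chem_comp_descriptor.descriptor
7PH SMILES_CANONICAL CACTVS 3.385 "CCCCCCCCCCCCCCCC(=O)OC[C@H](COP(O)(O)=O)OC(=O)CCCCCCCCCCCCCCC"
#
data_TRD
_chem_comp.id TRD
_chem_comp.name TRIDECANE
loop_
_pdbx_chem_comp_descriptor.comp_id
_pdbx_chem_comp_descriptor.type
_pdbx_chem_comp_descriptor.program
_pdbx_chem_comp_descriptor.program_version
_pdbx_chem_comp_descriptor.descriptor
TRD SMILES_CANONICAL CACTVS 3.341 CCCCCCCCCCCCC
#
data_HOH
_chem_comp.id HOH
_chem_comp.name WATER
loop_
_pdbx_chem_comp_descriptor.comp_id
_pdbx_chem_comp_descriptor.type
_pdbx_chem_comp_descriptor.program
_pdbx_chem_comp_descriptor.program_version
_pdbx_chem_comp_descriptor.descriptor
HOH SMILES_CANONICAL CACTVS 3.341 O
#
data_UNX
_chem_comp.id UNX
_chem_comp.name "UNKNOWN ATOM OR ION"
#
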