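# Membrane topology of human COQ2 (UniProt Q96H96, 371-aa isoform).
# SYNTHETIC RECONSTRUCTION: segment order, membrane sides, and which
# residues fall in which segment follow the published description
# (nine transmembrane helices S1-S9; N-terminus and the S2-S3, S4-S5,
# S6-S7, S8-S9 loops on the matrix side; C-terminus and the S1-S2,
# S3-S4, S5-S6, S7-S8 loops in the intermembrane space; variant and
# motif locations per segment), but the exact helix boundary residues
# are approximate - they were not published as numbers.
label	start	end	side
N-term	1	84	matrix
S1	85	105	membrane
S1-S2	106	112	intermembrane
S2	113	131	membrane
S2-S3	132	152	matrix
S3	153	172	membrane
S3-S4	173	183	intermembrane
S4	184	193	membrane
S4-S5	194	203	matrix
S5	204	221	membrane
S5-S6	222	231	intermembrane
S6	232	246	membrane
S6-S7	247	280	matrix
S7	281	300	membrane
S7-S8	301	308	intermembrane
S8	309	328	membrane
S8-S9	329	336	matrix
S9	337	356	membrane
C-term	357	371	intermembrane
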