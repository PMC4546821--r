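# Example batch configuration: one [section] per data file.
# '#' starts a comment at line start or after whitespace, so #RRGGBB
# colour literals inside values are safe.

[bone_marrow_day1]
data = data/bone_marrow_stats.tsv     # delimited text with a header
id_column = GeneID
syscode = SysCode                     # a column name, or a fixed code like L
species = Mus musculus
pathways = pathways/                  # a .gpml file or a directory of them
mapping = mapping/Mm_L_En.tsv         # optional identifier mapping TSV
criterion = [P.Value] < 0.05          # optional; enables Z-score ranking
gradient = logFC:-1:#0000FF,0:#FFFFFF,1:#FF0000
rule = P.Value:#00FF00:[P.Value] <= 0.05
out = results/bone_marrow_day1

[spleen_day1]
data = data/spleen_stats.tsv
id_column = GeneID
syscode = L
species = Mus musculus
pathways = pathways/
criterion = [P.Value] < 0.05
gradient = logFC:-1:#0000FF,0:#FFFFFF,1:#FF0000
out = results/spleen_day1
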