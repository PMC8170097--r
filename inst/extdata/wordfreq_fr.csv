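word,frequency
le,0.035
la,0.028
les,0.022
un,0.0132
une,0.0115
des,0.0123
et,0.019
est,0.0087
sont,0.0018
il,0.011
elle,0.0049
ils,0.0027
je,0.013
on,0.0044
nous,0.0028
vous,0.0072
dans,0.0052
sur,0.0034
de,0.047
à,0.02
avec,0.0028
pour,0.0062
sous,0.00055
par,0.0032
que,0.014
qui,0.0062
ce,0.0069
cette,0.0021
garçon,0.000063
fille,0.00035
femme,0.00042
mère,0.00024
maman,0.00019
dame,0.000087
cuisine,0.000091
biscuit,0.0000095
gâteau,0.0000398
bocal,0.0000029
pot,0.0000302
tabouret,0.0000032
évier,0.0000027
assiette,0.0000234
eau,0.00035
fenêtre,0.000085
placard,0.0000182
vaisselle,0.0000112
rideau,0.0000115
rideaux,0.0000199
torchon,0.0000035
frère,0.00015
sœur,0.0000955
fils,0.00019
extérieur,0.000052
jardin,0.00011
dehors,0.000072
tombe,0.000091
déborde,0.0000047
coule,0.0000209
lave,0.0000214
sèche,0.0000087
prend,0.00019
vole,0.0000257
regarde,0.00013
voit,0.000083
euh,0.00032
oui,0.0011
alors,0.00072
voilà,0.00032
petit,0.00051
grand,0.00044
occupé,0.0000324
plein,0.00012
mouillé,0.0000072
tout,0.0035
quelque,0.00023
chose,0.00055
ici,0.00044
aussi,0.00098
très,0.00091
là,0.0011
pas,0.0072
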