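word,frequency
the,0.053
a,0.021
an,0.0018
and,0.028
is,0.0095
are,0.0047
was,0.0046
there,0.0028
he,0.0069
she,0.0042
it,0.012
they,0.0042
i,0.021
you,0.017
we,0.0046
his,0.0035
her,0.0032
in,0.017
on,0.0059
of,0.032
to,0.024
from,0.0026
with,0.0055
at,0.0041
into,0.00091
over,0.0012
under,0.00034
by,0.0032
for,0.0083
that,0.011
this,0.0055
boy,0.00011
girl,0.00017
woman,0.00025
mother,0.00021
lady,0.000091
kitchen,0.000083
cookie,0.000029
cookies,0.000032
jar,0.0000115
stool,0.0000042
sink,0.000028
plate,0.000038
water,0.00055
window,0.00017
cupboard,0.0000069
dish,0.0000245
dishes,0.0000263
curtain,0.0000117
curtains,0.0000135
towel,0.0000302
brother,0.00013
sister,0.00012
son,0.00019
daughter,0.0001
outside,0.00024
garden,0.000056
yard,0.000055
falling,0.000072
washing,0.0000263
stealing,0.0000166
watching,0.00016
taking,0.00023
reaching,0.0000324
standing,0.00011
running,0.00013
drying,0.0000056
overflowing,0.0000011
see,0.0017
going,0.00091
doing,0.00046
uh,0.00072
um,0.00038
oh,0.0013
well,0.0019
little,0.00055
big,0.00042
busy,0.000046
full,0.00013
wet,0.0000427
dirty,0.0000468
all,0.0046
lot,0.00044
something,0.00074
everything,0.00029
here,0.0015
very,0.0017
also,0.0011
just,0.0028
too,0.0014
not,0.0083
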