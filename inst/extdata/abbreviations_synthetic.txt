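# synthetic lexicalized abbreviation inventory
St.p.
Z.n.
ca.
Pat.
o.B.
bds.
li.
re.
max.
unauff.
Amb.
sek.
tgl.
ggf.
z.B.
bzw.
inkl.
Lab.
Tbl.
u.a.
Exz.
lat.
med.
n.
St.
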