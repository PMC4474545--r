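# synthetic closed-class word list
am
an
auch
auf
aus
bei
bis
das
dem
den
der
des
die
ein
eine
einem
eines
es
im
in
ist
kann
kein
keine
mit
nach
oder
ohne
sich
sie
sind
soll
sowie
und
unter
von
vor
war
waren
wir
wird
wurde
wurden
zum
zur
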