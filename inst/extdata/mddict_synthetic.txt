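# synthetic German-like medical vocabulary (generated, not harvested)
Basalbereich
Basaldicke
Basalentfernung
Basalexzision
Basalkontrolle
Basalstruktur
Basalveränderung
Befundanteil
Befunddicke
Befunddurchmesser
Befundentfernung
Befundgewebe
Befundknoten
Befundkontrolle
Befundläsion
Befundrandsaum
Befundstruktur
Befundveränderung
beschrieben
bestand
besteht
Biopsieanteil
Biopsiebefund
Biopsiebereich
Biopsiebildung
Biopsiedicke
Biopsiedurchmesser
Biopsieläsion
Biopsierandsaum
Biopsieveränderung
derbendes
derblicher
derbt
derbte
dokumentiert
druckschmerzhafend
druckschmerzhafende
druckschmerzhafendes
druckschmerzhafig
druckschmerzhafige
druckschmerzhafliche
druckschmerzhaft
druckschmerzhaftes
durchgeführt
empfohlen
entfernt
entzündend
entzündende
entzündig
entzündte
entzündtes
erfolgte
erforderend
erforderende
erforderendes
erforderig
erforderige
erforderlich
erforderliche
erforderte
erfordertes
exulzerierend
exulzerierende
exulzerierendes
exulzerierig
exulzerierige
exulzerierlich
exulzerierliche
exulzeriert
exulzeriertes
Exzisionanteil
Exzisionbildung
Exzisiondicke
Exzisiondurchmesser
Exzisionexzision
Exzisiongewebe
Exzisionknoten
Exzisionkontrolle
Exzisionrandsaum
Exzisionzeichnung
Gewebebereich
Gewebeentfernung
Gewebeexzision
Gewebekontrolle
Geweberegion
Gewebestruktur
Gewebezeichnung
Haaranteil
Haarbereich
Haardurchmesser
Haarentfernung
Haarknoten
Haarkontrolle
Haarläsion
Haarregion
Haarstruktur
Hautbereich
Hautbildung
Hautdicke
Hautexzision
Hautkontrolle
Hautläsion
Hautrandsaum
Hautstruktur
Hautveränderung
imponiert
Infiltratbefund
Infiltratbereich
Infiltratdicke
Infiltratexzision
Infiltratknoten
Infiltratläsion
Infiltratrandsaum
Infiltratstruktur
Infiltratzeichnung
Knotenanteil
Knotenbefund
Knotenbereich
knotend
knotende
knotendes
Knotendicke
Knotenentfernung
Knotenexzision
Knotenkontrolle
Knotenläsion
Knotenrandsaum
Knotenstruktur
Knotenzeichnung
knotlich
knotliche
knotte
knottes
Kontrollbereich
kontrolliert
Kontrollknoten
Kontrollkontrolle
Kontrollrandsaum
Kontrollregion
Kontrollstruktur
Kontrollveränderung
Kontrollzeichnung
Leberbefund
Leberexzision
Lebergewebe
Leberknoten
Leberkontrolle
Leberläsion
Leberstruktur
Leberveränderung
Lungenanteil
Lungenbefund
Lungenbereich
Lungengewebe
Lungenkontrolle
Lungenläsion
Lungenstruktur
Lungenveränderung
Lymphbildung
Lymphdicke
Lymphdurchmesser
Lymphentfernung
Lymphkontrolle
Lymphläsion
Lymphzeichnung
Melanomanteil
Melanombildung
Melanomentfernung
Melanomexzision
Melanomgewebe
Melanomknoten
Melanomregion
Melanomstruktur
Melanomveränderung
Melanomzeichnung
melanozytende
melanozytig
melanozytige
melanozytlich
melanozytt
melanozytte
melanozyttes
Muttermalanteil
Muttermalbefund
Muttermalbereich
Muttermalbildung
Muttermaldurchmesser
Muttermalexzision
Muttermalgewebe
Muttermalknoten
Muttermalläsion
Muttermalregion
Muttermalveränderung
Nagelbefund
Nageldicke
Nageldurchmesser
Nagelentfernung
Nagelexzision
Nagelkontrolle
Nagelläsion
Nagelregion
Nagelveränderung
Narbenanteil
Narbenbereich
Narbenbildung
Narbendicke
Narbendurchmesser
Narbenexzision
Narbengewebe
Narbenknoten
Narbenkontrolle
Narbenrandsaum
Narbenveränderung
narbigende
narbigig
narbigige
narbiglich
narbigte
narbigtes
oberflächlende
oberflächlendes
oberflächlig
oberflächlige
oberflächlliche
oberflächllicher
oberflächlt
oberflächlte
oberflächltes
pathologende
pathologendes
pathologig
pathologlich
pathologliche
pathologt
pathologte
pathologtes
persistiert
Pigmentbildung
Pigmentdurchmesser
Pigmententfernung
pigmentierend
pigmentierendes
pigmentierig
pigmentierlicher
pigmentiert
Pigmentkontrolle
Pigmentläsion
Pigmentstruktur
Pigmentveränderung
Plattenepithelbefund
Plattenepithelbereich
Plattenepitheldicke
Plattenepithelentfernung
Plattenepithelexzision
Plattenepithelknoten
Plattenepithelrandsaum
Plattenepithelveränderung
Plattenepithelzeichnung
Punktiondurchmesser
Punktionentfernung
Punktionexzision
Punktiongewebe
Punktionkontrolle
Punktionregion
Punktionstruktur
Punktionveränderung
Randbereich
Randdicke
Randdurchmesser
Randentfernung
Randexzision
Randgewebe
Randknoten
Randkontrolle
Randläsion
Randregion
Randstruktur
Randveränderung
Randzeichnung
regulärend
regulärende
regulärendes
regulärig
regulärige
regulärlich
regulärlicher
regulärt
regulärte
reseziert
Rippenbefund
Rippenbereich
Rippenbildung
Rippendicke
Rippenexzision
Rippenknoten
Rippenkontrolle
Rippenläsion
Rippenregion
Rippenstruktur
Schnittbefund
Schnittbildung
Schnittdurchmesser
Schnittkontrolle
Schnittstruktur
Schnittveränderung
suspektend
suspektig
suspektige
suspektlich
suspektliche
suspektt
suspektte
suspekttes
tastbarendes
tastbarig
tastbarlich
tastbarlicher
tastbarte
tastbartes
tastet
Therapiebereich
Therapiebildung
Therapiedicke
Therapiedurchmesser
Therapieknoten
Therapieläsion
Therapierandsaum
Tumoranteil
Tumorbefund
Tumorbereich
Tumorbildung
Tumorkontrolle
Tumorrandsaum
Tumorstruktur
unauffällend
unauffällende
unauffällige
unauffällt
unauffälltes
vergrößerende
vergrößerige
vergrößerlich
vergrößerliche
vergrößerlicher
vergrößertes
verschiebend
verschiebende
verschiebendes
verschieblich
verschiebliche
verschieblicher
verschiebt
verschiebte
verschiebtes
Wundbefund
Wundbildung
Wundentfernung
Wundknoten
Wundkontrolle
Wundläsion
Wundrandsaum
Wundveränderung
Wundzeichnung
zeigt
zeigte
Zellanteil
Zellbereich
Zelldicke
Zellentfernung
Zellgewebe
Zellläsion
Zellrandsaum
Zellstruktur
Zellveränderung
Zellzeichnung
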