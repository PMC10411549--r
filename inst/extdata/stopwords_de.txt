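# German stopword list, semcoh resource v1
# general-purpose function-word inventory; matching is case-insensitive
aber
alle
allem
allen
aller
alles
als
also
am
an
andere
anderen
auch
auf
aus
bei
beim
bin
bis
bist
da
damit
dann
das
dass
dein
deine
dem
den
denn
der
des
dessen
dich
die
dies
diese
diesem
diesen
dieser
dieses
dir
doch
dort
du
durch
ein
eine
einem
einen
einer
eines
er
es
etwas
euer
eure
für
gegen
gewesen
hab
habe
haben
hat
hatte
hatten
hier
hin
hinter
ich
ihm
ihn
ihnen
ihr
ihre
im
in
indem
ins
ist
ja
jede
jedem
jeden
jeder
jedes
jetzt
kann
kein
keine
keinem
keinen
können
könnte
machen
man
mein
meine
mich
mir
mit
muss
musste
nach
nicht
nichts
noch
nun
nur
ob
oder
ohne
sehr
sein
seine
seinem
seinen
sich
sie
sind
so
sollte
sondern
über
um
und
uns
unser
unter
vom
von
vor
war
waren
warum
was
weil
weiter
welche
welchem
welchen
welcher
wenn
werde
werden
wie
wieder
will
wir
wird
wirst
wo
wollen
wollte
während
würde
würden
zu
zum
zur
zwar
zwischen
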