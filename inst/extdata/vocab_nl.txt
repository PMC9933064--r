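de
het
een
en
van
ik
je
dat
die
in
te
zijn
op
niet
met
voor
als
maar
dan
er
ze
bij
ook
naar
om
uit
aan
dus
wel
nog
wat
heel
goed
mooi
huis
dag
jaar
mens
tijd
werk
leven
vraag
woord
ding
plek
stad
dorp
land
water
lucht
zon
maan
week
maand
uur
minuut
moment
verhaal
familie
moeder
vader
kind
zoon
dochter
broer
zus
vriend
buurman
verzorger
dokter
zuster
kamer
tafel
stoel
deur
raam
tuin
straat
winkel
markt
brood
kaas
melk
koffie
thee
soep
appel
peer
bloem
boom
gras
vogel
hond
kat
paard
koe
schaap
fiets
auto
trein
bus
boot
weg
brug
kerk
school
boek
krant
brief
foto
muziek
lied
stem
oor
oog
hand
voet
hoofd
hart
been
arm
rug
buik
gezicht
haar
mond
neus
praten
zeggen
vertellen
vragen
antwoorden
luisteren
horen
zien
kijken
lopen
zitten
staan
liggen
slapen
eten
drinken
koken
wassen
werken
spelen
zingen
lezen
schrijven
denken
weten
vinden
voelen
willen
kunnen
moeten
mogen
gaan
komen
blijven
wonen
helpen
zorgen
geven
nemen
maken
doen
houden
vallen
opstaan
wachten
beginnen
stoppen
vandaag
morgen
gisteren
vroeger
later
altijd
nooit
soms
vaak
samen
alleen
binnen
buiten
boven
onder
links
rechts
dichtbij
veraf
groot
klein
oud
jong
nieuw
warm
koud
licht
donker
stil
druk
blij
verdrietig
moe
sterk
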