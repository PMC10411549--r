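# German verbal-filler list, semcoh resource v1
# hesitation and backchannel vocalizations removed before scoring
ehm
äh
ähm
öh
öhm
hm
hmm
mhm
mh
em
uh
uhm
eh
tja
naja
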