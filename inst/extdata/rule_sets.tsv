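# Curated transcription of published siRNA design-rule position preferences
# on the SENSE strand (positions 1..19, 5'->3'). verdict +1 = the set marks
# that nucleotide favourable at that position, -1 = unfavourable; positions
# a set is silent on are simply absent (encoded 0). Best-effort curation of
# the cited design guidelines; edit or replace via loadRuleTable().
# version: 1
rule_set	position	nucleotide	verdict
reynolds	3	A	1
reynolds	10	U	1
reynolds	19	A	1
reynolds	13	G	-1
reynolds	19	G	-1
reynolds	19	C	-1
uitei	1	G	1
uitei	1	C	1
uitei	19	A	1
uitei	19	U	1
uitei	1	A	-1
uitei	1	U	-1
uitei	19	G	-1
uitei	19	C	-1
amarzguioui	1	G	1
amarzguioui	1	C	1
amarzguioui	6	A	1
amarzguioui	19	A	1
amarzguioui	19	U	1
amarzguioui	1	U	-1
amarzguioui	19	G	-1
hsieh	19	U	1
hsieh	11	G	-1
hsieh	19	G	-1
jagla	1	G	1
jagla	1	C	1
jagla	10	A	1
jagla	10	U	1
jagla	19	A	1
jagla	19	U	1
jagla	19	G	-1
jagla	19	C	-1
takasaki	3	A	1
takasaki	10	U	1
takasaki	13	A	1
takasaki	13	G	-1
takasaki	19	G	-1
elbashir	19	A	1
elbashir	19	U	1
elbashir	19	G	-1
khvorova	19	A	1
khvorova	19	U	1
khvorova	1	A	-1
khvorova	1	U	-1
holen	10	A	1
holen	10	U	1
holen	1	U	-1
shabalina	10	U	1
shabalina	19	A	1
shabalina	19	U	1
shabalina	19	G	-1
shabalina	19	C	-1
matveeva	6	A	1
matveeva	19	A	1
matveeva	19	U	1
matveeva	19	C	-1
hohjoh	19	U	1
hohjoh	19	G	-1
hohjoh	19	C	-1
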