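history domestic violence	pos
rib fracture	pos
retinal hemorrhage	pos
altered mental status	pos
vertebral fracture	pos
illicit drug use	pos
limited motion	pos
unwitnessed	pos
inconsistent	pos
non accidental trauma	pos
delay seeking care	pos
bruising	pos
witnessed	neg
consistent mechanism	neg
accidental fall	neg
employment	neg
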