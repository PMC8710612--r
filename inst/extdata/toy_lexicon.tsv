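good	pos
happy	pos
fun	pos
nice	pos
great	pos
joy	pos
lovely	pos
glad	pos
bright	pos
warm	pos
bad	neg
sad	neg
fear	neg
worry	neg
pain	neg
gloom	neg
tired	neg
cold	neg
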