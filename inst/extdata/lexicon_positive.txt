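pleasant
beautiful
wonderful
bright
fresh
quiet
peaceful
happy
comfortable
charming
spectacular
refreshing
tasty
delicious
poetic
calm
impressive
serene
lovely
enjoyable
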