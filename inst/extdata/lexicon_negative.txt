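noisy
ugly
dirty
crowded
moldy
boring
unpleasant
smelly
dull
neglected
shabby
gloomy
bad
broken
messy
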