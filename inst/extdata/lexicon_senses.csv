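sense,term
vision,scenery
vision,colorful
vision,bright
vision,green
vision,golden
vision,blossom
smell,fragrance
smell,aroma
smell,scent
smell,odor
hearing,quiet
hearing,birdsong
hearing,rustle
hearing,silent
touch,smooth
touch,soft
touch,breeze
touch,cool
taste,tasty
taste,delicious
taste,sweet
feeling,happy
feeling,comfortable
feeling,relaxed
feeling,pleasant
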