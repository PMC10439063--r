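pattern,n_levels,index,tau
equidistant,5,1,-3
equidistant,5,2,-1
equidistant,5,3,1
equidistant,5,4,3
left-biased,5,1,-1
left-biased,5,2,1
left-biased,5,3,3
left-biased,5,4,5
right-biased,5,1,-5
right-biased,5,2,-3
right-biased,5,3,-1
right-biased,5,4,1
edge-biased,5,1,-1
edge-biased,5,2,-0.35
edge-biased,5,3,0.35
edge-biased,5,4,1
centre-biased,5,1,-4
centre-biased,5,2,-1.5
centre-biased,5,3,1.5
centre-biased,5,4,4
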