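target,tp,fn,tn,fp
fa,68,8,4912,12
rt,595,13,4384,8
pc,383,22,4581,14
dt,241,5,4748,6
dc,202,15,4741,42
ie,133,9,4848,10
at,415,34,4543,8
non-asynchrony,2542,52,2328,78
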