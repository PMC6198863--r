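model positive_feedback
const S = 1
species X = 0
species Y = 0
param k1 = 4
param k2 = 0.80000000000000004
param k3 = 0.40000000000000002
param k4 = 0.25
param ki = 0.20000000000000001
production_X:  -> X ; k1*S*(0.1 + Y)/(ki + Y)
decay_X: X ->  ; k2*X
production_Y:  -> Y ; k3*X
decay_Y: Y ->  ; k4*Y
end
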