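model smad_model_3
species D = 1
species Smad7 = 0.050000000000000003
species Ski = 0.050000000000000003
param kV = 2
param km = 0.5
param I50 = 0.29999999999999999
param kski = 0.5
param kdeg7 = 0.80000000000000004
param kdegs = 0.29999999999999999
param kfb = 1.5
Smad7Transcription:  -> Smad7 ; kV*D/(km + D) * I50/(I50 + Ski)
SkiTranscription:  -> Ski ; kski*D
Smad7Deg: Smad7 ->  ; kdeg7*Smad7
SkiDeg: Ski ->  ; kdegs*Ski^2
Feedback: D + Smad7 ->  ; kfb*Smad7*D
end
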