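failure_id,factor,q,o,p
F1,S,0.429,0.679,0.900
F2,S,0.343,0.593,0.843
F3,S,0.350,0.600,0.843
F4,S,0.357,0.607,0.829
F5,S,0.293,0.543,0.779
F6,S,0.364,0.614,0.850
F1,O,0.414,0.664,0.893
F2,O,0.400,0.650,0.871
F3,O,0.314,0.564,0.800
F4,O,0.357,0.607,0.843
F5,O,0.314,0.564,0.807
F6,O,0.364,0.614,0.843
F1,D,0.429,0.679,0.893
F2,D,0.364,0.614,0.821
F3,D,0.314,0.564,0.807
F4,D,0.336,0.586,0.807
F5,D,0.329,0.579,0.807
F6,D,0.407,0.657,0.836
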