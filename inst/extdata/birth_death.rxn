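# Open birth-death process: Poisson(10) stationary law
species A init 0
reaction b: 0 -> A @ 10
reaction d: A -> 0 @ 1
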