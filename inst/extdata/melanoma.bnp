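n=10 p=0.01
gene=1 regs=3,5,6 out=01000110
gene=2 regs=1,3,5 out=01001000
gene=3 regs=7 out=01
gene=4 regs=1,2,4 out=01010100
gene=5 regs=4,9 out=1011
gene=6 regs=4,7,10 out=11000001
gene=7 regs=7 out=01
gene=8 regs=1,5,9 out=10001111
gene=9 regs=1,4,7,10 out=1011111100110111
gene=10 regs=3 out=10
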