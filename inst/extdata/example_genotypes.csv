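sample_id,x,y,group,loc01_1,loc01_2,loc02_1,loc02_2,loc03_1,loc03_2,loc04_1,loc04_2,loc05_1,loc05_2
s0001,-97.5616010867824,90.9927430479604,,12,12,10,12,11,11,10,10,12,12
s0002,-6.09211179265223,179.520555612344,,12,12,10,12,12,12,10,10,10,12
s0003,165.972335562271,-136.527439897191,,12,12,10,12,12,12,10,13,12,12
s0004,-7.40114685747341,6.21808777936822,,12,12,12,12,11,12,10,10,10,11
s0005,39.2106171382987,-74.0430619661525,,12,12,12,12,11,12,13,13,10,12
s0006,205.184409844009,-2.3187381625984,,12,12,12,12,11,11,10,13,10,12
s0007,20.8494188631832,132.215953288284,,12,12,12,12,11,12,10,12,10,12
s0008,144.052327014873,-143.53120560967,,12,12,10,12,11,12,10,13,10,10
s0009,9944.05275920477,3.31926741527417,,10,12,12,12,11,11,10,10,10,10
s0010,9953.79811535853,-20.503696151005,,10,12,12,12,11,13,10,10,10,12
s0011,9874.31994504886,-123.73042469098,,10,10,12,12,11,12,10,13,10,10
s0012,10183.1370652595,-62.8107897060432,,10,12,12,12,11,11,10,10,10,10
s0013,9876.53943335219,-29.0002469746903,,10,10,12,12,11,11,10,13,10,12
s0014,10095.307324276,20.5871154492903,,10,10,12,12,11,11,10,13,10,10
s0015,9992.49623395667,58.8459031590374,,10,10,12,12,11,11,13,13,10,10
s0016,9941.75286930771,-102.433401474893,,10,10,12,12,11,11,10,10,10,10
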