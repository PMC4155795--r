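# SWC generated by arborsim
# fixture: toy-tree T1
# index type x y z radius parent
1 1 0 0 0 5 -1
2 3 10 0 0 1 1
3 3 20 0 0 1 2
4 3 10 10 0 1 2
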