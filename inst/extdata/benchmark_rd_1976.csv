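region,NW,N,NE,SW,S,SE,Sofia,Total
NW,-0.56,-0.09,0.69,-0.19,0.02,0.44,0.33,-0.04
N,-0.32,-0.51,-0.50,0.64,0.38,0.34,1.92,-0.14
NE,0.15,-0.12,-0.56,0.66,0.60,-0.16,2.03,-0.12
SW,0.43,2.50,2.43,-0.42,2.02,3.01,4.08,1.23
S,0.15,0.64,1.05,-0.04,-0.53,-0.53,2.19,-0.15
SE,1.78,1.84,0.69,1.27,0.33,-0.56,2.70,0.31
Sofia,-0.78,-0.43,-0.29,-0.71,-0.39,-0.55,NA,-0.52
Total,-0.43,-0.15,-0.25,-0.30,-0.23,-0.34,1.72,-0.12
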