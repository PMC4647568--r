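((marmoratus:5,pygmaeus:5):19,((ivanbureschi:7,karelinii:7):3.5,((carnifex:9,macedonicus:9):0.5,(cristatus:8.5,dobrogicus:8.5):1):1):13.5);
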