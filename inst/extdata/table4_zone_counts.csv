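species,zone,modal,nonmodal
ivanbureschi,central,150,25
ivanbureschi,fringe,110,76
carnifex,central,53,13
carnifex,fringe,37,20
macedonicus,central,51,16
macedonicus,fringe,122,37
cristatus,central,98,24
cristatus,fringe,130,34
dobrogicus,central,42,15
dobrogicus,fringe,67,92
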