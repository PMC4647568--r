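species,n,any_transformation,cervical_complete,cervical_incomplete,sacral_left,sacral_right,thoracic_to_sacral_incomplete
marmoratus,58,5,0,1,1,3,0
pygmaeus,55,1,0,0,1,0,0
ivanbureschi,361,25,1,3,6,12,3
karelinii,43,1,0,0,0,1,0
carnifex,123,8,0,0,6,2,0
macedonicus,226,14,0,1,8,4,1
cristatus,286,16,2,1,10,3,0
dobrogicus,216,13,0,0,7,6,0
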