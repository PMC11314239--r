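variety_id,group,char1,char2,char3,char4,char5,char6,char7,char8,char9,char10,char11,char12,char13,char14,char15,char16,char17,char18,char19,char20,char21,char22,char23,char24,char25,char26,char27,char28,char29,char30,char31,char32
toy01,landrace,1,2,3,3,3,3,3,3,3,2,5,5,1,5,7,2,1,3,3,7,3,5,5,4,9,5,2,1,2,3,3,2
toy02,landrace,2,2,2,3,3,3,3,3,2,3,5,3,2,7,7,2,3,1,3,7,3,5,7,3,7,7,1,2,1,3,3,2
toy03,landrace,2,2,1,3,2,5,3,3,3,3,5,5,1,1,7,2,3,3,4,5,1,5,5,2,9,3,1,2,1,2,5,2
toy04,landrace,2,2,2,3,2,3,3,5,2,3,5,5,3,3,5,2,3,3,4,5,4,7,7,3,9,5,1,1,1,2,3,2
toy05,landrace,2,2,3,3,2,3,3,3,2,3,3,5,1,7,7,2,3,1,4,7,4,7,5,3,7,5,1,2,1,3,3,2
toy06,cultivated,2,2,1,2,1,3,3,3,2,3,3,3,3,3,7,2,5,3,3,7,2,5,7,2,5,7,2,2,3,2,3,2
toy07,cultivated,2,1,1,3,1,5,3,3,2,3,3,5,1,5,7,2,3,3,3,3,2,3,7,3,7,7,2,2,2,1,4,2
toy08,cultivated,3,2,1,2,1,5,2,3,2,3,3,3,3,7,7,2,3,3,3,7,4,5,5,3,7,7,1,1,3,2,4,2
toy09,cultivated,2,2,1,3,1,5,2,3,1,2,3,5,1,5,7,2,3,1,3,5,4,5,5,3,7,5,2,3,1,1,3,2
toy10,cultivated,2,2,1,2,1,5,2,3,2,3,3,5,1,7,7,2,5,3,4,7,3,5,7,3,5,9,1,3,3,2,4,2
toy11,cultivated,2,1,1,2,1,5,3,3,3,2,5,5,1,5,7,2,5,1,3,5,1,3,5,4,5,7,2,1,3,2,4,2
toy12,cultivated,2,2,2,3,1,3,2,3,2,3,3,5,2,3,7,2,3,3,4,5,3,5,3,3,3,5,2,2,3,2,4,2
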