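>1
ILTSSSPEGARDFLVPSRLNPGKFYALPQAPQQFKQLI
>2
VFFSFLLGFTKGKFYALPQAPQTILSNLFMVSGFDKYFTNC
>3
PSRLNPGKFYALPQAPQQFKQLIMVSGFDRYFQIAPCFR
>4
DFLVPSRLHKGKFYALPQAPQQFKQLVMVSGFDKYFQI
>5
RFFSSFLGLHKGKFYALPQAPQQFKLTCHGIRVILSN
>6
GARDFLVPSRLNPGKFYALPQAPQQFKQLIMVSGFD
>7
ARDFLVPSRLNPGKFYALPQAPQQFKQLVMVSGFDRYFQI
>8
DFLVPSRLNPGKFYALPQAPQQFKQLIMVSGFDKYFQIA
>9
DFLVPSRLHKGKFYALPQAPQQFKQLVMVSGFDKYFQL
>10
SRLNPGKFYALPQAPQQFKQLIMVSGFDRYFQIAPCF
>11
YFLVPSRLHKGKFYALPQAPQQFKLTCHGIRVILSNC
>12
QAGCGLYCSKQIKSWKFYALPQAPQQFKQLIMI
>13
LNPGKFYALPQAPQQFKQLIMVSGFDRYFQIAPCFR
>14
SFKSRKFYALPQAPQQFKQLIMVSGFDRYFQIAPCFG
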