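species,CONV,IPW,BD
Aureobasidium pullulans,70.4,63.2,52.5
Cryptococcus magnus,9.2,7.9,6.6
Cryptococcus carnescens,2.0,2.6,3.3
Cryptococcus oeirensis,1.0,2.6,1.6
Cryptococcus laurentii,-,2.6,2.5
Cryptococcus flavescens,-,-,3.3
Rhodotorula slooffiae,4.1,-,4.1
Sporobolomyces roseus,6.1,3.9,3.3
Cryptococcus saitoi,-,-,0.8
Rhodosporidium diobovatum,-,-,5.7
Kazachstania sp.,-,-,4.9
Pichia caribbica,-,-,1.6
Candida parapsilosis,-,-,1.6
Meira geulakonigii,-,-,1.6
Exophiala sp.,-,-,1.6
Sporisorium sp.,-,-,2.5
Ustilago sp.,-,-,2.5
Candida sp.,1.0,-,-
Saccharomycete sp.,1.0,-,-
Bullera dendrophila,3.1,-,-
Rhodotorula glutinis,-,7.9,-
Cryptococcus randhawii,-,2.6,-
Issatchenkia terricola,1.0,6.6,-
Rhodotorula nothofagi,1.0,-,-
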