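# Illustrative heart-failure preferred-term list (narrow-style, exact terms).
# NOT the licensed MedDRA "cardiac failure (SMQ)" content; users supply their
# own SMQ export for real analyses. One PT per line, optional tab + PT code.
Cardiac failure	10007554
Cardiac failure acute	10007556
Cardiac failure congestive	10007559
Acute left ventricular failure	10063081
Acute right ventricular failure	10063082
Left ventricular failure	10024119
Right ventricular failure	10039163
Ventricular failure	10047290
Cardiogenic shock	10007625
Low cardiac output syndrome	10024848
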