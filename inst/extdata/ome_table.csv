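atc_prefix,substance,route,factor,factor_units
N02AA01,morphine,oral,1,mg_per_mg
N02AA01,morphine,parenteral,3,mg_per_mg
N02AA03,hydromorphone,oral,5,mg_per_mg
N02AA05,oxycodone,oral,1.5,mg_per_mg
N02AA05,oxycodone,parenteral,3,mg_per_mg
N02AA55,oxycodone and naloxone,oral,1.5,mg_per_mg
N02AB02,pethidine,oral,0.4,mg_per_mg
N02AB03,fentanyl,transdermal,100,mg_per_mg_delivered
N02AB03,fentanyl,nasal,160,mg_per_mg
N02AE01,buprenorphine,transdermal,75,mg_per_mg_delivered
N02AE01,buprenorphine,sublingual,40,mg_per_mg
N02AX02,tramadol,oral,0.1,mg_per_mg
N02AX06,tapentadol,oral,0.3,mg_per_mg
N02AJ13,tramadol and paracetamol,oral,0.1,mg_per_mg
N07BC01,buprenorphine,sublingual,40,mg_per_mg
N07BC02,methadone,oral,4.7,mg_per_mg
N07BC51,buprenorphine and naloxone,sublingual,40,mg_per_mg
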