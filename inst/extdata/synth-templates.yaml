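# Dutch label-text building blocks for the synthetic corpus generator.
# Base vocabulary is deliberately free of every nutrient search term,
# generic vitamin/mineral wording, and remark phrase, so that scenario
# fragments fully control what the classifier can find.
base_ingredients:
  - water
  - suiker
  - tarwebloem
  - volkorenmeel
  - zout
  - gist
  - plantaardige olie
  - zonnebloemolie
  - palmolie
  - aroma
  - natuurlijk aroma
  - sojabonen
  - havermout
  - rijst
  - cacaopoeder
  - glucosestroop
  - gerstemout
  - maltodextrine
  - erwteneiwit
  - kokosolie
  - citroensap
  - appelsapconcentraat
  - johannesbroodpitmeel
  - dextrose
harmless_additive_fragments:
  - "emulgator (sojalecithine)"
  - "conserveermiddel (sorbinezuur)"
  - "zuurteregelaar (citroenzuur)"
  - "stabilisator (guarpitmeel)"
  - "verdikkingsmiddel (xanthaangom)"
food_name_stems:
  - halvarine
  - ontbijtgranen
  - sojadrank
  - haverdrank
  - vruchtensap
  - limonade
  - mueslireep
  - vleesvervanger
  - margarine
  - yoghurtdrank
  - broodje
  - pastamaaltijd
  - groentesoep
  - chocolademelk
  - smeerkaas
brand_suffixes:
  - huismerk
  - premium
  - original
  - naturel
  - extra
fortificant_forms:
  calcium: [calcium, calciumcarbonaat, calciumlactaat, tricalciumcitraat, calciumfosfaat, calciumcitraat]
  folic_acid: [foliumzuur, folaat, foliumzuur (b11)]
  vitamin_b12: [vitamine b12, cyanocobalamine, b12, cobalamine]
  zinc: [zink, zinkgluconaat, zinksulfaat, zinkcitraat, zink lactaat]
plain_names:
  calcium: calcium
  folic_acid: foliumzuur
  vitamin_b12: vitamine b12
  zinc: zink
additive_context_templates:
  - "stabilisator: %s"
  - "verdikkingsmiddel (%s)"
  - "antioxidant: %s"
  - "zuurteregelaar (%s)"
  - "emulgator (%s)"
additive_compound_forms:
  calcium: [calciumcarbonaat, calciumfosfaat, calciumalginaat, calciumlactaat]
  zinc: [zinkgluconaat, zinkoxide]
natural_remark_templates:
  - "rijk aan %s"
  - "bron van %s"
generic_fragments:
  - "vitaminen en mineralen"
  - "vitamines en mineralen"
  - "toegevoegde vitaminen en mineralen"
  - mineralen
legal_name_fortified_templates:
  - "%s verrijkt met %s"
  - "%s met toegevoegd %s"
particulars_fortified_templates:
  - "bevat toegevoegd %s"
  - "verrijkt met %s"
mineral_water_fragment: "natuurlijk mineraalwater (calcium %s mg/l, magnesium 25 mg/l, natrium 10 mg/l)"
ineligible_food_names:
  - "zuigelingenvoeding 1"
  - "opvolgmelk 2"
  - "dieetvoeding medisch"
  - "maaltijdvervanger afslank"
  - "multivitamine tabletten"
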