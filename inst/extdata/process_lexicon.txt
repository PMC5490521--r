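# Nature-changing food processes (lemmas, one per line).
# Seeded from the FoodEx2 documentation's examples (canning, smoking, frying,
# baking) plus common cooking/preservation processes; extend freely.
can
smoke
fry
bake
boil
cook
roast
grill
steam
stew
dry
freeze
pickle
salt
cure
ferment
mill
grind
toast
mash
preserve
concentrate
dehydrate
tin
marinate
poach
braise
blanch
bottle
candy
distil
refine
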