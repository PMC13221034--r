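subcategory_label,entry_category
bathtub,bathtub
tub,bathtub
koala,bear
brown_bear,bear
black_bear,bear
polar_bear,bear
sloth_bear,bear
red_panda,bear
giant_panda,bear
house_finch,bird
snowbird,bird
indigo_finch,bird
robin,bird
bulbul,bird
jay,bird
magpie,bird
chickadee,bird
water_ouzel,bird
ringlet_butterfly,butterfly
monarch_butterfly,butterfly
cabbage_butterfly,butterfly
sulphur_butterfly,butterfly
lycaenid_butterfly,butterfly
indian_elephant,elephant
african_elephant,elephant
goldfish,fish
crampfish,fish
devilfish,fish
eel,fish
coho,fish
rock_beauty,fish
anemone_fish,fish
sturgeon,fish
garfish,fish
lionfish,fish
pufferfish,fish
crash_helmet,helmet
football_helmet,helmet
gasmask,helmet
mailbox,mailbox
coffee_mug,mug
cellular_telephone,phone
dial_telephone,phone
payphone,phone
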