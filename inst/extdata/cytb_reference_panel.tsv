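code	species	common_name	enzyme	fragments
cm	Thunnus alalunga	albacore tuna	Eco147I	233,124
cm	Thunnus alalunga	albacore tuna	HinfI	109,52,196
cm	Thunnus alalunga	albacore tuna	MboI	357
cm	Thunnus alalunga	albacore tuna	XagI	357
cm	Thunnus alalunga	albacore tuna	HindII	-
hu	Thunnus albacares	yellowfin tuna	Eco147I	357
hu	Thunnus albacares	yellowfin tuna	HinfI	109,52,196
hu	Thunnus albacares	yellowfin tuna	MboI	357
hu	Thunnus albacares	yellowfin tuna	XagI	101,256
hu	Thunnus albacares	yellowfin tuna	HindII	-
lq	Thunnus thynnus	Atlantic bluefin tuna	Eco147I	357
lq	Thunnus thynnus	Atlantic bluefin tuna	HinfI	109,248
lq	Thunnus thynnus	Atlantic bluefin tuna	MboI	62,295
lq	Thunnus thynnus	Atlantic bluefin tuna	XagI	357
lq	Thunnus thynnus	Atlantic bluefin tuna	HindII	-
ms	Thunnus maccoyii	southern bluefin tuna	Eco147I	357
ms	Thunnus maccoyii	southern bluefin tuna	HinfI	109,248
ms	Thunnus maccoyii	southern bluefin tuna	MboI	357
ms	Thunnus maccoyii	southern bluefin tuna	XagI	357
ms	Thunnus maccoyii	southern bluefin tuna	HindII	-
da	Tetrapturus audax	striped marlin	Eco147I	124,74,159
da	Tetrapturus audax	striped marlin	HinfI	196,161
da	Tetrapturus audax	striped marlin	MboI	357
da	Tetrapturus audax	striped marlin	XagI	357
da	Tetrapturus audax	striped marlin	HindII	-
ji	Xiphias gladius	swordfish	Eco147I	283,74
ji	Xiphias gladius	swordfish	HinfI	196,161
ji	Xiphias gladius	swordfish	MboI	357
ji	Xiphias gladius	swordfish	XagI	357
ji	Xiphias gladius	swordfish	HindII	-
dd	Thunnus obesus	bigeye tuna	Eco147I	357
dd	Thunnus obesus	bigeye tuna	HinfI	109,52,196
dd	Thunnus obesus	bigeye tuna	MboI	357
dd	Thunnus obesus	bigeye tuna	XagI	357
dd	Thunnus obesus	bigeye tuna	HindII	150,10,197
jy	Katsuwonus pelamis	skipjack tuna	Eco147I	357
jy	Katsuwonus pelamis	skipjack tuna	HinfI	109,52,196
jy	Katsuwonus pelamis	skipjack tuna	MboI	357
jy	Katsuwonus pelamis	skipjack tuna	XagI	357
jy	Katsuwonus pelamis	skipjack tuna	HindII	357
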