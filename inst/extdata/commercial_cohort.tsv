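id	label	true_species
Slq-2	Atlantic bluefin tuna	Thunnus thynnus
Slq-4	Atlantic bluefin tuna	Thunnus thynnus
Slq-5	Atlantic bluefin tuna	Thunnus thynnus
Slq-6	Atlantic bluefin tuna	Thunnus thynnus
Slq-7	Atlantic bluefin tuna	Thunnus thynnus
Slq-8	Atlantic bluefin tuna	Thunnus thynnus
Slq-10	Atlantic bluefin tuna	Thunnus thynnus
Slq-11	Atlantic bluefin tuna	Thunnus thynnus
Slq-24	Atlantic bluefin tuna	Thunnus alalunga
Slq-31	Atlantic bluefin tuna	Thunnus alalunga
Sms-10	southern bluefin tuna	Thunnus maccoyii
Sms-11	southern bluefin tuna	Thunnus maccoyii
Sms-12	southern bluefin tuna	Thunnus maccoyii
Sms-13	southern bluefin tuna	Thunnus maccoyii
Sms-14	southern bluefin tuna	Thunnus maccoyii
Sms-15	southern bluefin tuna	Thunnus maccoyii
Shu-1	yellowfin tuna	Thunnus albacares
Shu-2	yellowfin tuna	Thunnus albacares
Shu-3	yellowfin tuna	Thunnus albacares
Shu-4	yellowfin tuna	Thunnus albacares
Shu-5	yellowfin tuna	Thunnus albacares
Shu-6	yellowfin tuna	Thunnus albacares
Shu-7	yellowfin tuna	Thunnus albacares
Shu-8	yellowfin tuna	Thunnus albacares
Shu-9	yellowfin tuna	Thunnus albacares
Shu-11	yellowfin tuna	Thunnus albacares
Shu-12	yellowfin tuna	Thunnus obesus
Shu-17	yellowfin tuna	Thunnus obesus
Shu-27	yellowfin tuna	Thunnus obesus
Sdd-1	bigeye tuna	Thunnus obesus
Sdd-2	bigeye tuna	Thunnus obesus
Sdd-3	bigeye tuna	Thunnus obesus
Sdd-4	bigeye tuna	Thunnus obesus
Sdd-5	bigeye tuna	Thunnus obesus
Sdd-6	bigeye tuna	Thunnus obesus
Sdd-7	bigeye tuna	Thunnus obesus
Sdd-8	bigeye tuna	Thunnus obesus
Sdd-14	bigeye tuna	Tetrapturus audax
Sdd-15	bigeye tuna	Tetrapturus audax
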