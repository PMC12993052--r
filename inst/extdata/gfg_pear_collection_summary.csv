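location,final_samples,trees,accessions,molecular_samples,pomological_samples
Hermann Cordes Nursery KG,167,166,95,173,184
Competence Centre of Fruit Production - Lake Constance,293,293,147,293,293
State Education and Research Institute for Viticulture and Pomology Weinsberg,46,46,24,48,50
Julius Kuehn Institute - Institute for Breeding Research on Fruit Crops,250,250,132,256,243
State Institute for Agriculture and Horticulture Saxony-Anhalt,168,168,56,168,168
Federal Plant Variety Office - Testing Station Wurzen,261,243,109,268,270
Nonprofit Association: Teaching and Research Institution for Horti- and Arboriculture,242,242,137,249,250
Triesdorf Agricultural Education Centre,510,510,271,538,540
References Brogdale,8,0,8,8,0
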