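species	gene	status
Rozella allomycis	atp8	absent
Rozella allomycis	nad1	absent
Rozella allomycis	nad2	absent
Rozella allomycis	nad3	absent
Rozella allomycis	nad4	absent
Rozella allomycis	nad4L	absent
Rozella allomycis	nad5	absent
Rozella allomycis	nad6	absent
Rozella allomycis	rps3	absent
Rhizopus oryzae	rps3	absent
Hyaloraphidium curvatum	rps3	absent
Candida albicans	rps3	absent
Grosmannia piceiperda	atp6	not_available
Grosmannia piceiperda	atp8	not_available
Grosmannia piceiperda	atp9	not_available
Grosmannia piceiperda	cob	not_available
Grosmannia piceiperda	cox1	not_available
Grosmannia piceiperda	cox2	not_available
Grosmannia piceiperda	cox3	not_available
Grosmannia piceiperda	nad1	not_available
Grosmannia piceiperda	nad2	not_available
Grosmannia piceiperda	nad3	not_available
Grosmannia piceiperda	nad4	not_available
Grosmannia piceiperda	nad4L	not_available
Grosmannia piceiperda	nad5	not_available
Grosmannia piceiperda	nad6	not_available
Saccharomyces cerevisiae	nad1	absent
Saccharomyces cerevisiae	nad2	absent
Saccharomyces cerevisiae	nad3	absent
Saccharomyces cerevisiae	nad4	absent
Saccharomyces cerevisiae	nad4L	absent
Saccharomyces cerevisiae	nad5	absent
Saccharomyces cerevisiae	nad6	absent
Schizosaccharomyces pombe	nad1	absent
Schizosaccharomyces pombe	nad2	absent
Schizosaccharomyces pombe	nad3	absent
Schizosaccharomyces pombe	nad4	absent
Schizosaccharomyces pombe	nad4L	absent
Schizosaccharomyces pombe	nad5	absent
Schizosaccharomyces pombe	nad6	absent
Schizosaccharomyces pombe	rps3	absent
Tilletia indica	rps3	absent
Tolypocladium inflatum	cox1	present
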