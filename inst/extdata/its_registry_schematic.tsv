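# Curated registry of the additional ITS sites described for euglenids
# (eITS1-eITS13, after Euglena gracilis) and kinetoplastids (kITS1-kITS7,
# after Trypanosoma cruzi / trypanosomatids), with the three cross-lineage
# shared positions encoded as identical flanking-anchor pairs:
# eITS10/kITS5, eITS11/kITS6, eITS13/kITS7.
#
# SYNTHETIC placement: the flanking helix anchors below use yeast-style LSU
# helix numbers but are schematic stand-ins, not transcribed secondary-
# structure coordinates; only the site inventory, the domain assignment and
# the shared-position structure are curated. Site numbering runs past the
# per-lineage 28S ITS counts (12 euglenid, 5 kinetoplastid) because the
# first site(s) of each series flank the 5.8S rRNA rather than interrupting
# the 28S: eITS1 and kITS1-kITS2 are assigned domain 5.8S accordingly.
site_id	lineage	left_anchor	right_anchor	domain
eITS1	euglenid	H2	H3	5.8S
eITS2	euglenid	H16	H17	LSU
eITS3	euglenid	H21	H22	LSU
eITS4	euglenid	H28	H29	LSU
eITS5	euglenid	H34	H35	LSU
eITS6	euglenid	H38	H39	LSU
eITS7	euglenid	H43	H44	LSU
eITS8	euglenid	H47	H48	LSU
eITS9	euglenid	H50	H51	LSU
eITS10	euglenid	H54	H55	LSU
eITS11	euglenid	H63	H64	LSU
eITS12	euglenid	H68	H69	LSU
eITS13	euglenid	H79	H80	LSU
kITS1	kinetoplastid	H1	H2	5.8S
kITS2	kinetoplastid	H4	H5	5.8S
kITS3	kinetoplastid	H30	H31	LSU
kITS4	kinetoplastid	H45	H46	LSU
kITS5	kinetoplastid	H54	H55	LSU
kITS6	kinetoplastid	H63	H64	LSU
kITS7	kinetoplastid	H79	H80	LSU
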