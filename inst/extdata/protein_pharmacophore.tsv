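# Protein pharmacophore atom-typing table, version 1.
# classes: all pharmacophore classes an atom realises (comma-separated);
# primary: the single class used for per-residue composition counts.
# Formal charges are counted once per charged group on its central atom
# (LYS NZ, ARG CZ, ASP CG, GLU CD); terminal N/O atoms of those groups
# keep donor/acceptor as their primary class but carry the charge class
# in their class set for signature typing.
residue	atom	classes	primary
ALA	N	hb_donor	hb_donor
ALA	CA	hydrophobic	hydrophobic
ALA	C	neutral	neutral
ALA	O	hb_acceptor	hb_acceptor
ALA	CB	hydrophobic	hydrophobic
ARG	N	hb_donor	hb_donor
ARG	CA	hydrophobic	hydrophobic
ARG	C	neutral	neutral
ARG	O	hb_acceptor	hb_acceptor
ARG	CB	hydrophobic	hydrophobic
ARG	CG	hydrophobic	hydrophobic
ARG	CD	hydrophobic	hydrophobic
ARG	NE	positive,hb_donor	hb_donor
ARG	CZ	positive	positive
ARG	NH1	positive,hb_donor	hb_donor
ARG	NH2	positive,hb_donor	hb_donor
ASN	N	hb_donor	hb_donor
ASN	CA	hydrophobic	hydrophobic
ASN	C	neutral	neutral
ASN	O	hb_acceptor	hb_acceptor
ASN	CB	hydrophobic	hydrophobic
ASN	CG	neutral	neutral
ASN	OD1	hb_acceptor	hb_acceptor
ASN	ND2	hb_donor	hb_donor
ASP	N	hb_donor	hb_donor
ASP	CA	hydrophobic	hydrophobic
ASP	C	neutral	neutral
ASP	O	hb_acceptor	hb_acceptor
ASP	CB	hydrophobic	hydrophobic
ASP	CG	negative	negative
ASP	OD1	negative,hb_acceptor	hb_acceptor
ASP	OD2	negative,hb_acceptor	hb_acceptor
CYS	N	hb_donor	hb_donor
CYS	CA	hydrophobic	hydrophobic
CYS	C	neutral	neutral
CYS	O	hb_acceptor	hb_acceptor
CYS	CB	hydrophobic	hydrophobic
CYS	SG	sulfur	sulfur
GLN	N	hb_donor	hb_donor
GLN	CA	hydrophobic	hydrophobic
GLN	C	neutral	neutral
GLN	O	hb_acceptor	hb_acceptor
GLN	CB	hydrophobic	hydrophobic
GLN	CG	hydrophobic	hydrophobic
GLN	CD	neutral	neutral
GLN	OE1	hb_acceptor	hb_acceptor
GLN	NE2	hb_donor	hb_donor
GLU	N	hb_donor	hb_donor
GLU	CA	hydrophobic	hydrophobic
GLU	C	neutral	neutral
GLU	O	hb_acceptor	hb_acceptor
GLU	CB	hydrophobic	hydrophobic
GLU	CG	hydrophobic	hydrophobic
GLU	CD	negative	negative
GLU	OE1	negative,hb_acceptor	hb_acceptor
GLU	OE2	negative,hb_acceptor	hb_acceptor
GLY	N	hb_donor	hb_donor
GLY	CA	hydrophobic	hydrophobic
GLY	C	neutral	neutral
GLY	O	hb_acceptor	hb_acceptor
HIS	N	hb_donor	hb_donor
HIS	CA	hydrophobic	hydrophobic
HIS	C	neutral	neutral
HIS	O	hb_acceptor	hb_acceptor
HIS	CB	hydrophobic	hydrophobic
HIS	CG	aromatic	aromatic
HIS	CD2	aromatic	aromatic
HIS	CE1	aromatic	aromatic
HIS	ND1	aromatic,donor_acceptor	donor_acceptor
HIS	NE2	aromatic,donor_acceptor	donor_acceptor
ILE	N	hb_donor	hb_donor
ILE	CA	hydrophobic	hydrophobic
ILE	C	neutral	neutral
ILE	O	hb_acceptor	hb_acceptor
ILE	CB	hydrophobic	hydrophobic
ILE	CG1	hydrophobic	hydrophobic
ILE	CG2	hydrophobic	hydrophobic
ILE	CD1	hydrophobic	hydrophobic
LEU	N	hb_donor	hb_donor
LEU	CA	hydrophobic	hydrophobic
LEU	C	neutral	neutral
LEU	O	hb_acceptor	hb_acceptor
LEU	CB	hydrophobic	hydrophobic
LEU	CG	hydrophobic	hydrophobic
LEU	CD1	hydrophobic	hydrophobic
LEU	CD2	hydrophobic	hydrophobic
LYS	N	hb_donor	hb_donor
LYS	CA	hydrophobic	hydrophobic
LYS	C	neutral	neutral
LYS	O	hb_acceptor	hb_acceptor
LYS	CB	hydrophobic	hydrophobic
LYS	CG	hydrophobic	hydrophobic
LYS	CD	hydrophobic	hydrophobic
LYS	CE	hydrophobic	hydrophobic
LYS	NZ	positive,hb_donor	positive
MET	N	hb_donor	hb_donor
MET	CA	hydrophobic	hydrophobic
MET	C	neutral	neutral
MET	O	hb_acceptor	hb_acceptor
MET	CB	hydrophobic	hydrophobic
MET	CG	hydrophobic	hydrophobic
MET	SD	sulfur	sulfur
MET	CE	hydrophobic	hydrophobic
PHE	N	hb_donor	hb_donor
PHE	CA	hydrophobic	hydrophobic
PHE	C	neutral	neutral
PHE	O	hb_acceptor	hb_acceptor
PHE	CB	hydrophobic	hydrophobic
PHE	CG	aromatic,hydrophobic	aromatic
PHE	CD1	aromatic,hydrophobic	aromatic
PHE	CD2	aromatic,hydrophobic	aromatic
PHE	CE1	aromatic,hydrophobic	aromatic
PHE	CE2	aromatic,hydrophobic	aromatic
PHE	CZ	aromatic,hydrophobic	aromatic
PRO	N	hb_donor	hb_donor
PRO	CA	hydrophobic	hydrophobic
PRO	C	neutral	neutral
PRO	O	hb_acceptor	hb_acceptor
PRO	CB	hydrophobic	hydrophobic
PRO	CG	hydrophobic	hydrophobic
PRO	CD	hydrophobic	hydrophobic
SER	N	hb_donor	hb_donor
SER	CA	hydrophobic	hydrophobic
SER	C	neutral	neutral
SER	O	hb_acceptor	hb_acceptor
SER	CB	hydrophobic	hydrophobic
SER	OG	donor_acceptor	donor_acceptor
THR	N	hb_donor	hb_donor
THR	CA	hydrophobic	hydrophobic
THR	C	neutral	neutral
THR	O	hb_acceptor	hb_acceptor
THR	CB	hydrophobic	hydrophobic
THR	OG1	donor_acceptor	donor_acceptor
THR	CG2	hydrophobic	hydrophobic
TRP	N	hb_donor	hb_donor
TRP	CA	hydrophobic	hydrophobic
TRP	C	neutral	neutral
TRP	O	hb_acceptor	hb_acceptor
TRP	CB	hydrophobic	hydrophobic
TRP	CG	aromatic,hydrophobic	aromatic
TRP	CD1	aromatic,hydrophobic	aromatic
TRP	CD2	aromatic,hydrophobic	aromatic
TRP	NE1	aromatic,hb_donor	hb_donor
TRP	CE2	aromatic,hydrophobic	aromatic
TRP	CE3	aromatic,hydrophobic	aromatic
TRP	CZ2	aromatic,hydrophobic	aromatic
TRP	CZ3	aromatic,hydrophobic	aromatic
TRP	CH2	aromatic,hydrophobic	aromatic
TYR	N	hb_donor	hb_donor
TYR	CA	hydrophobic	hydrophobic
TYR	C	neutral	neutral
TYR	O	hb_acceptor	hb_acceptor
TYR	CB	hydrophobic	hydrophobic
TYR	CG	aromatic,hydrophobic	aromatic
TYR	CD1	aromatic,hydrophobic	aromatic
TYR	CD2	aromatic,hydrophobic	aromatic
TYR	CE1	aromatic,hydrophobic	aromatic
TYR	CE2	aromatic,hydrophobic	aromatic
TYR	CZ	aromatic,hydrophobic	aromatic
TYR	OH	donor_acceptor	donor_acceptor
VAL	N	hb_donor	hb_donor
VAL	CA	hydrophobic	hydrophobic
VAL	C	neutral	neutral
VAL	O	hb_acceptor	hb_acceptor
VAL	CB	hydrophobic	hydrophobic
VAL	CG1	hydrophobic	hydrophobic
VAL	CG2	hydrophobic	hydrophobic
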