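((((taxon001,taxon002)clade0003-clade0003-clade0003,(taxon003,taxon004)clade0003-clade0003-clade0004,taxon005)clade0003-clade0003,((taxon006,taxon007)clade0003-clade0007-clade0007,(taxon008,taxon009)clade0003-clade0007-clade0008,taxon010)clade0003-clade0007)clade0003,(((taxon011,taxon012)clade0012-clade0012-clade0012,taxon013,taxon014)clade0012-clade0012,((taxon015,taxon016)clade0012-clade0016-clade0016,taxon017)clade0012-clade0016,(taxon018,taxon019,taxon020)clade0012-clade0019)clade0012)root;
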