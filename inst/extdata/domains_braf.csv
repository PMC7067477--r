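# BRAF kinase domain: the activation segment runs from the DFG motif
# (residues 594-596) to the APE motif (residues 621-623), author
# numbering shared by 4MNE chain B and 4H58 chain C. Everything outside
# the segment is classified as "other" by classify_interdomain().
domain,start,end
activation_segment,594,623
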