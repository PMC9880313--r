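{"transcript_id":"BTK_like","exon_lengths":[100,80,90,80,90,80,90,120,130,130,130,130,130,130,130,130,130,130,350],"cds_start_tx":89,"cds_end_tx":2068,"spliced_seq":"ACTTAGCAACTACATCTCATATACGTGTTTCCTTGTGGCCTTGTAGGTATATAAAGTCATAAATCGCAGACGCCGGAAGCTTTGTGACATGATGAGTAGCTGGGACGATGTGTCGCTCTTCAAAGGCCTCAATAACAGATTTAATCTAACCTGGTCTCCCCACTTGGGCAGGGGGTGCAGTTTTTCATCTTTTTCCAACTGCTCGGATGCGAACCCTAACTCCGGGATAGGCAGGCATGAGAATCATGGAGGACGCACCGCTGAGAGAGGCTGGACATGCCTAAATAGACTTATGCTTAATGCGGGCTCTCGTCCTAGTAGCCTAACTGTAGACCATGGGACGGACAGGGACGATGAGGCTAGAGGAAAACCGTTCCCCCAGGCGGCAGCGCGAAGGGGACAGATTCCATTAGCATCCTATCTCAGGTTCTTCGCTGTACCCAGTTGTCGCTCGTATATCGTAGGTGTCATATTCGATGAATCCGAGTTGACGGTCGGTCATTGGGGCAAAACATTACGACTGGTGAGCAAACCCTTCTCTGGAGAACATAATGCGTCACGCCGCTCTAAAAGGTTGCTTTTACCTGGTAACGTAGGACGACTCTGCCGTGGTCGCCTGGTATCCAAGAATGGGTCAATGTTATCCGCGAGCTATCCCTACAGGGATCATATTGAAGAGCTAAAAGTTTCCGTCACAGGTCCGACGCATGTGAAAGCTTGGAATCTCTGCTGGGACTTAGTGTGTAATAGTCCCTTGTGCGCTACCTGTGGGGTTAAGGGAGATGAGTGCTTAGACGCCTTTGCTTCCAAAGGCAACGATGGAAGGCGTTCCACCAAGTCGCATTTTTGCCTAGACGTGACTAGAGGATGCCTTGGACGCTGGTTCAAGCCATGCCCGGAAAACCGGTTATCCAAGCCTAGAAGAGACCGTTTAACAAGGGAACATCCCAAGCAGACCGGCATCTCTCTGAAATATTTCGAGCCTAATGAGACCGTGTTCGGTGTAGCCGTGTTTGCTAAGGGGCGCGTCACCTATCCACGCACTCGTCCACCTACCTTGATTTTACATCTGGTTTGCGTATCAGAGGCCGAGAAGAGCGTGGTTGTTTGTCATGCCCGCAGGATCATCAATTTAGATCACTTTACCGCAGAAAGTGTTCGCAGCCTTCGATCGCGCGGTACATCAACTAGATCCGTTAATAAAAGCTCTATAGCTGCTTGTCGTTGTCGTTGGTGCCGTATGATCTATTGCACAACGAAGGATTCCCACACCCACGCTTCTCGGAATGTAGGGAGATGGCACGTACCCGTCAGAACTTTGCTATTAACATTTACTCGACTACCTTTGGTGAACCTATCTCGCCTAGTATGTAAGTTACCTCGATCTCGCATAAGATGTAGAGTACCAGCACTAACACAGACCCTTAGGCAGTTTCTATCCCGTACAACTCATGCTGCCGGGATAGTACATGTTTTCGCAGTGTGGCTACGGGAACTGCCCAACGGCATTGACGGACGATTGAATACGGCCTGCATCCTGCTCACTATCGACTGCTCTGTGACTCCAGAGACGAACATGTTGTACTCGTATCTTTCGAGCTCTCATTTCTTCGTATACCGGAATGCACAGGCTTTGAGTACACATTGCTCAGGACATCTCACAACTCAACATATTTTGCGCCTTATTTTACCAGGAACACGTGCCTCCCTCTTGGCACCCATAATCAACCACGCCCGAGTCTGGAACCTTCATACGTCTTCCCACATAACGCGTCGCACCCGTACTCCACTGCGTGTTATCATTGAAACTCAGTGTGGCCCGACAGTTGCGGCCACTTGGCTCAAATTATTGAGATCAAGATGCCTGTTTTGCCATCCCCGTGCCAGGAAATTAAGAGACCAGACAATGGGATATGTCGTCGGGGTCTCATCAATATGCCCTAGGCTGCGGTTCCGGCGAAAGCCGTCTAGCAAGCAAATTGGGTGCTTGGTGCCACGACCGGTGGCGGGCCGTGTACCACCCCGCGTCTATGCTCAAAGTGCAACACGCAACGCTGTTTCGTCGTAGCTTAACCTCACACGGGGTTCTAGAACTGAAGGCTAACGTGGATACTGTGATGCATGACGTCTGCCTAACGTAGATGCAGTTTTTATCGGACACGAGTCAGCTCCGAGATGCTTTTACTAGCGGTAAGATGAAGGAGAGACAACCAATGGGAGCCCGGCATCTCAAGCTTGGCAGGTATTCTAGGACGGGGTGATTGAGTAGACCGTACCAACTGCAATACTCGAGCTTGAAAGTCCTAAGCGACATAAACGACCTGACGTAAACTCCTCAGATTCTGCGATTCCCGGTGTTTCATTCACTTCCCCCGCGTAG"}
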