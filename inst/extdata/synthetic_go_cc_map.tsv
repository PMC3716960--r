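accession	go_id
21735621	GO:0005622
21735621	GO:0005739
21735621	GO:0005768
19923206	GO:0005622
19923206	GO:0005737
4507677	GO:0005622
4507677	GO:0005811
32313593	GO:0005576
32313593	GO:0005874
75709200	GO:0005739
75709200	GO:0005737
4506885	GO:0005576
4506885	GO:0005578
4758638	GO:0005737
4758638	GO:0005622
4758012	GO:0005737
4503483	GO:0005737
4503571	GO:0005737
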