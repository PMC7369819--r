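# Curated list of genes regulating IL-1beta production or implicated in gouty
# inflammation, with the direction of each gene's reported effect on IL-1beta.
# This list externalizes the literature-review step of the candidate filter;
# the pipeline intersects promoter EWAS hits with these genes.
genes:
  - gene: PGGT1B
    category: il1b_production
    il1b_direction: down
  - gene: INSIG1
    category: il1b_production
    il1b_direction: down
  - gene: ANGPTL2
    category: il1b_production
    il1b_direction: up
  - gene: JNK1
    category: il1b_production
    il1b_direction: up
  - gene: UBAP1
    category: expressed_macrophage_il1b
    il1b_direction: down
  - gene: RECK
    category: expressed_macrophage_il1b
    il1b_direction: down
  - gene: NPC2
    category: expressed_macrophage_il1b
    il1b_direction: down
  - gene: RAPTOR
    category: expressed_macrophage_il1b
    il1b_direction: down
  - gene: CNTN5
    category: gouty_inflammation
    il1b_direction: unknown
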