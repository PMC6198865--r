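<?xml version="1.0" encoding="UTF-8"?>
<recPhylo>
  <spTree>
    <phylogeny>
      <clade>
        <name>A</name>
        <clade>
          <name>B</name>
        </clade>
        <clade>
          <name>C</name>
        </clade>
      </clade>
    </phylogeny>
  </spTree>
  <recGeneTree>
    <phylogeny rooted="true">
      <clade>
        <name>n1</name>
        <eventsRec>
          <branchingOut speciesLocation="C"></branchingOut>
        </eventsRec>
        <clade>
          <name>LOST</name>
          <eventsRec>
            <loss speciesLocation="C"></loss>
          </eventsRec>
        </clade>
        <clade>
          <name>gene_seq_2</name>
          <eventsRec>
            <transferBack destinationSpecies="B"></transferBack>
            <leaf speciesLocation="B"></leaf>
          </eventsRec>
        </clade>
      </clade>
    </phylogeny>
  </recGeneTree>
</recPhylo>
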