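<?xml version="1.0" encoding="UTF-8"?>
<recPhylo>
  <spTree>
    <phylogeny>
      <clade>
        <name>A</name>
        <clade>
          <name>B</name>
          <geography>
            <area>
              <name>Lyon</name>
              <description>type locality</description>
              <value>0.9</value>
              <source>observed</source>
            </area>
            <area>
              <name>Montpellier</name>
              <source>inferred by Beast</source>
            </area>
          </geography>
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
        <name>gene_seq_1</name>
        <eventsRec>
          <leaf speciesLocation="B"></leaf>
        </eventsRec>
        <geography>
          <area>
            <name>Lyon</name>
            <source>observed</source>
          </area>
        </geography>
      </clade>
    </phylogeny>
  </recGeneTree>
</recPhylo>
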