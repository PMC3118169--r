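<?xml version="1.0" encoding="UTF-8"?>
<Diagram xmlns="urn:mimml:1.0" width="360" height="160">
  <EntityGlyph visId="CaMK" type="simple-physical-entity" label="CaMK" centerX="90" centerY="80" width="70" height="28"/>
  <EntityGlyph visId="P" type="modifier" label="P" centerX="290" centerY="80" width="24" height="16"/>
  <InteractionGlyph visId="cleavP" type="cleavage" metadataRefs="pub1">
    <Point x="126" y="80" arrowHead="none" visRef="CaMK"/>
    <Point x="276" y="80" arrowHead="cleavage-mark" visRef="P"/>
  </InteractionGlyph>
  <MimBio>
    <dc-creator>mimml examples</dc-creator>
    <dc-identifier>example-cleavage</dc-identifier>
    <dc-title>Cleavage of phosphate from CaMK</dc-title>
    <CrossReference visId="pub1" db="PubMed" dbId="16890956" relationship="see-also"/>
  </MimBio>
</Diagram>
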