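<?xml version="1.0" encoding="UTF-8"?>
<Diagram xmlns="urn:mimml:1.0" width="640" height="420">
  <EntityGlyph visId="CaM" type="simple-physical-entity" label="calmodulin" centerX="540" centerY="260" width="70" height="28"/>
  <EntityGlyph visId="CaMK" type="simple-physical-entity" label="CaMK" centerX="300" centerY="60" width="70" height="28"/>
  <EntityGlyph visId="CaMK_kin" type="entity-feature" label="kinase domain" centerX="180" centerY="130" width="90" height="24" parentRef="CaMK"/>
  <EntityGlyph visId="CaMK_reg" type="entity-feature" label="regulation domain" centerX="420" centerY="130" width="110" height="24" parentRef="CaMK"/>
  <EntityGlyph visId="P" type="modifier" label="P" centerX="300" centerY="330" width="24" height="16"/>
  <EntityGlyph visId="Substrates" type="simple-physical-entity" label="Substrates" centerX="120" centerY="330" width="70" height="28"/>
  <EntityGlyph visId="cplxCaM" type="explicit-complex" lineRef="bindCaM" linePosition="0.5"/>
  <InteractionGlyph visId="bindCaM" type="non-covalent-reversible-binding">
    <Point x="540" y="246" arrowHead="barbed" visRef="CaM"/>
    <Point x="440" y="142" arrowHead="barbed" visRef="CaMK_reg"/>
  </InteractionGlyph>
  <InteractionGlyph visId="catKin" type="catalysis" metadataRefs="note1">
    <Point x="180" y="142" arrowHead="none" visRef="CaMK_kin"/>
    <Point x="223" y="318" arrowHead="catalysis-mark" visRef="phosSub.site"/>
  </InteractionGlyph>
  <InteractionGlyph visId="intra" type="non-covalent-reversible-binding" intramolecular="true">
    <Point x="225" y="130" arrowHead="barbed" visRef="CaMK_kin"/>
    <Point x="365" y="130" arrowHead="barbed" visRef="CaMK_reg"/>
  </InteractionGlyph>
  <InteractionGlyph visId="phosSub" type="covalent-modification">
    <Point x="288" y="330" arrowHead="none" visRef="P"/>
    <Point x="158" y="330" arrowHead="barbed" visRef="Substrates"/>
    <Anchor visId="phosSub.site" position="0.5"/>
  </InteractionGlyph>
  <MimBio>
    <dc-creator>mimml examples</dc-creator>
    <dc-identifier>example-camk</dc-identifier>
    <dc-title>CaMK regulation</dc-title>
    <Annotation visId="note1" comment="kinase activity of the catalytic domain">
      <PublicationXref db="PubMed" dbId="16890956"/>
    </Annotation>
  </MimBio>
</Diagram>
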