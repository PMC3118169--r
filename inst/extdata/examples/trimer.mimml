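<?xml version="1.0" encoding="UTF-8"?>
<Diagram xmlns="urn:mimml:1.0" width="400" height="260">
  <EntityGlyph visId="A" type="simple-physical-entity" label="A" centerX="70" centerY="60" width="70" height="28"/>
  <EntityGlyph visId="B" type="simple-physical-entity" label="B" centerX="280" centerY="60" width="70" height="28"/>
  <EntityGlyph visId="C" type="simple-physical-entity" label="C" centerX="175" centerY="200" width="70" height="28"/>
  <EntityGlyph visId="cplxAB" type="explicit-complex" lineRef="bindAB" linePosition="0.5"/>
  <EntityGlyph visId="cplxABC" type="explicit-complex" lineRef="bindABC" linePosition="0.5"/>
  <InteractionGlyph visId="bindAB" type="non-covalent-reversible-binding">
    <Point x="105" y="60" arrowHead="barbed" visRef="A"/>
    <Point x="245" y="60" arrowHead="barbed" visRef="B"/>
  </InteractionGlyph>
  <InteractionGlyph visId="bindABC" type="non-covalent-reversible-binding">
    <Point x="175" y="60" arrowHead="barbed" visRef="cplxAB"/>
    <Point x="175" y="186" arrowHead="barbed" visRef="C"/>
  </InteractionGlyph>
  <MimBio>
    <dc-creator>mimml examples</dc-creator>
    <dc-identifier>example-trimer</dc-identifier>
    <dc-title>Trimer A:B:C</dc-title>
  </MimBio>
</Diagram>
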