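<?xml version="1.0" encoding="UTF-8"?>
<!-- Grammar of the SVRL subset emitted by report_to_svrl(): a
     schematron-output root holding fired-rule elements (one per rule
     evaluated) and failed-assert elements (one per finding), each with a
     text message and diagnostic-reference children. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema"
           xmlns:svrl="http://purl.oclc.org/dsdl/svrl"
           targetNamespace="http://purl.oclc.org/dsdl/svrl"
           elementFormDefault="qualified">
  <xs:element name="schematron-output">
    <xs:complexType>
      <xs:sequence>
        <xs:element ref="svrl:fired-rule" minOccurs="0" maxOccurs="unbounded"/>
        <xs:element ref="svrl:failed-assert" minOccurs="0" maxOccurs="unbounded"/>
      </xs:sequence>
      <xs:attribute name="title" type="xs:string"/>
      <xs:attribute name="schemaVersion" type="xs:string"/>
    </xs:complexType>
  </xs:element>
  <xs:element name="fired-rule">
    <xs:complexType>
      <xs:attribute name="id" type="xs:string" use="required"/>
      <xs:attribute name="context" type="xs:string" use="required"/>
    </xs:complexType>
  </xs:element>
  <xs:element name="failed-assert">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="text" type="xs:string"/>
        <xs:element ref="svrl:diagnostic-reference" minOccurs="0"
                    maxOccurs="unbounded"/>
      </xs:sequence>
      <xs:attribute name="id" type="xs:string" use="required"/>
      <xs:attribute name="flag" type="xs:string" use="required"/>
      <xs:attribute name="location" type="xs:string" use="required"/>
    </xs:complexType>
  </xs:element>
  <xs:element name="diagnostic-reference">
    <xs:complexType>
      <xs:simpleContent>
        <xs:extension base="xs:string">
          <xs:attribute name="diagnostic" type="xs:string" use="required"/>
        </xs:extension>
      </xs:simpleContent>
    </xs:complexType>
  </xs:element>
</xs:schema>
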