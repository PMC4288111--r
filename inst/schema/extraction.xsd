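<?xml version="1.0" encoding="UTF-8"?>
<!-- ontoreg XML extraction export, version 1.
     One document per DataExtraction specification: a root `extraction`
     element holding one `record` per live instance of the target class.
     Non-recursive extractions reference object values by `ref` (instance
     id); recursive extractions inline referenced objects as nested records
     (each instance expanded at most once per document). -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="qualified">
  <xs:element name="extraction">
    <xs:complexType>
      <xs:sequence>
        <xs:element ref="record" minOccurs="0" maxOccurs="unbounded"/>
      </xs:sequence>
      <xs:attribute name="class" type="xs:anyURI" use="required"/>
      <xs:attribute name="recursive" type="xs:boolean" use="required"/>
    </xs:complexType>
  </xs:element>
  <xs:element name="record">
    <xs:complexType>
      <xs:sequence>
        <xs:element ref="field" minOccurs="0" maxOccurs="unbounded"/>
      </xs:sequence>
      <xs:attribute name="id" type="xs:integer" use="required"/>
      <xs:attribute name="class" type="xs:string" use="required"/>
    </xs:complexType>
  </xs:element>
  <xs:element name="field">
    <xs:complexType mixed="true">
      <xs:sequence>
        <xs:element ref="record" minOccurs="0"/>
      </xs:sequence>
      <xs:attribute name="name" type="xs:string" use="required"/>
      <xs:attribute name="ref" type="xs:integer"/>
      <xs:attribute name="resource" type="xs:anyURI"/>
      <xs:attribute name="code" type="xs:string"/>
    </xs:complexType>
  </xs:element>
</xs:schema>
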